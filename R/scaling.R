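#' Virtual listener for simulated categorical loudness scaling
#'
#' A generative stand-in for a participant in the aided loudness-scaling
#' measurement: the listener's true aided broadband loudness function per
#' stimulus plus a Gaussian response noise on the CU scale.
#'
#' @param functions Named list of [loudness_function()]s, one per stimulus
#'   (names among `"UEN5"`, `"UEN17"`, `"IFnoise"`).
#' @param response_noise_sd Standard deviation of the zero-mean Gaussian
#'   response noise in CU (>= 0).
#' @return An object of class `"virtual_listener"`.
#' @export
virtual_listener <- function(functions, response_noise_sd = 5) {
  stopifnot(is.list(functions), length(functions) >= 1L,
            !is.null(names(functions)),
            all(vapply(functions, inherits, logical(1), "loudness_function")),
            is.numeric(response_noise_sd), response_noise_sd >= 0)
  structure(list(functions = functions,
                 response_noise_sd = response_noise_sd),
            class = "virtual_listener")
}

#' @export
print.virtual_listener <- function(x, ...) {
  cat("Virtual listener: stimuli ", paste(names(x$functions), collapse = ", "),
      sprintf("; response noise sd %.1f CU\n", x$response_noise_sd), sep = "")
  invisible(x)
}

# round half-up to the nearest of the 11 response categories 0, 5, ..., 50
quantize_cu <- function(cu) {
  pmin(50, pmax(0, 5 * floor(cu / 5 + 0.5)))
}

#' Simulate one categorical loudness response
#'
#' Evaluates the listener's true loudness at the presentation level, adds
#' Gaussian response noise, and quantizes (half-up) to the nearest of the 11
#' response categories 0, 5, ..., 50 CU. Uses R's global random number
#' stream; seed with [set.seed()] for reproducibility.
#'
#' @param listener A [virtual_listener()].
#' @param stimulus_id Stimulus name present in `listener$functions`.
#' @param level Presentation level in dB SPL, in \[0, 120\].
#' @return Response category (multiple of 5 in \[0, 50\]).
#' @export
simulate_response <- function(listener, stimulus_id, level) {
  stopifnot(inherits(listener, "virtual_listener"),
            is.numeric(level), all(level >= 0), all(level <= 120))
  fn <- listener$functions[[stimulus_id]]
  if (is.null(fn)) stop("listener has no loudness function for stimulus ",
                        stimulus_id)
  cu <- cu_at_level(fn, level)
  if (listener$response_noise_sd > 0)
    cu <- cu + stats::rnorm(length(level), 0, listener$response_noise_sd)
  quantize_cu(cu)
}

#' Default configuration of the simulated adaptive scaling procedure
#'
#' @param trial_budget Total number of trials per stimulus (default 22,
#'   a shortened adaptive procedure).
#' @param phase1_step_db Level step of the bracketing phase in dB.
#' @param start_level_db First presentation level in dB SPL.
#' @param noise_sd_cu Listener response noise used by cohort simulation.
#' @return A named list.
#' @export
scaling_config <- function(trial_budget = 22, phase1_step_db = 10,
                           start_level_db = 65, noise_sd_cu = 5) {
  stopifnot(trial_budget >= 6, phase1_step_db > 0,
            start_level_db >= 0, start_level_db <= 120, noise_sd_cu >= 0)
  list(trial_budget = trial_budget, phase1_step_db = phase1_step_db,
       start_level_db = start_level_db, noise_sd_cu = noise_sd_cu)
}

#' Run a simulated adaptive categorical loudness scaling measurement
#'
#' Two-phase scheme standing in for the adaptive procedure used with
#' clinical audiometers. Phase 1 brackets the listener's usable dynamic
#' range: an ascending run from the start level (step `phase1_step_db`)
#' until a response of at least 45 CU or the 120 dB SPL cap, then a
#' descending run until a response of at most 5 CU or the 0 dB floor. Phase
#' 2 spends the remaining trial budget on levels evenly covering the
#' bracketed range, presented in pseudo-random order. Uses R's global RNG;
#' identical seed and config give an identical trial log.
#'
#' @param listener A [virtual_listener()].
#' @param stimulus_id Stimulus name.
#' @param config A [scaling_config()].
#' @return A data frame of class `"scaling_trials"` with columns
#'   `stimulus_id`, `trial_index`, `level_db_spl`, `response_cu`; exactly
#'   `config$trial_budget` rows.
#' @export
run_adaptive_scaling <- function(listener, stimulus_id = "IFnoise",
                                 config = scaling_config()) {
  stopifnot(inherits(listener, "virtual_listener"))
  step <- config$phase1_step_db
  levels <- numeric(0)
  responses <- numeric(0)
  present <- function(lv) {
    lv <- min(120, max(0, lv))
    levels <<- c(levels, lv)
    r <- simulate_response(listener, stimulus_id, lv)
    responses <<- c(responses, r)
    r
  }
  # phase 1a: ascending until loud
  lv <- config$start_level_db
  repeat {
    r <- present(lv)
    if (r >= 45 || lv >= 120) break
    lv <- min(120, lv + step)
  }
  upper <- levels[length(levels)]
  # phase 1b: descending until soft
  lv <- config$start_level_db - step
  repeat {
    if (lv < 0) lv <- 0
    r <- present(lv)
    if (r <= 5 || lv <= 0) break
    lv <- lv - step
  }
  lower <- levels[length(levels)]
  if (all(responses >= 45) && lower <= 0)
    stop("unusable dynamic range: listener saturated loud over the entire ",
         "level range")
  if (all(responses <= 5) && upper >= 120)
    stop("unusable dynamic range: listener never exceeded the softest ",
         "categories up to the level cap")
  n1 <- length(levels)
  n2 <- config$trial_budget - n1
  if (n2 < 0)
    stop("trial budget (", config$trial_budget, ") exhausted during ",
         "bracketing (", n1, " trials); increase trial_budget")
  if (n2 > 0) {
    grid <- seq(lower, upper, length.out = n2)
    for (lv in sample(grid)) present(lv)
  }
  structure(data.frame(stimulus_id = stimulus_id,
                       trial_index = seq_along(levels),
                       level_db_spl = levels,
                       response_cu = responses),
            class = c("scaling_trials", "data.frame"))
}
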