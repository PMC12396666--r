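# ---- skew-normal utilities (no skew-normal distribution in base R) -------

# density of SN(xi, omega, alpha)
dsn <- function(x, xi, omega, alpha) {
  z <- (x - xi) / omega
  2 / omega * stats::dnorm(z) * stats::pnorm(alpha * z)
}

# sampler via the convolution representation:
# z = delta*|u0| + sqrt(1-delta^2)*v with u0, v iid N(0,1)
rsn <- function(n, xi, omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- abs(stats::rnorm(n))
  v <- stats::rnorm(n)
  xi + omega * (delta * u0 + sqrt(1 - delta^2) * v)
}

sn_mean <- function(xi, omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  xi + omega * delta * sqrt(2 / pi)
}

sn_var <- function(omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  omega^2 * (1 - 2 * delta^2 / pi)
}

# grid-based CDF/quantile of a two-component skew-normal mixture
sn_mixture_quantile <- function(p, xi, omega, alpha, weights) {
  span <- 12 * omega
  x <- seq(min(xi) - span, max(xi) + span, length.out = 8192)
  dens <- weights[1] * dsn(x, xi[1], omega, alpha) +
    weights[2] * dsn(x, xi[2], omega, alpha)
  cdf <- cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(x))
  cdf <- c(0, cdf / cdf[length(cdf)])
  stats::approx(cdf, x, xout = p, ties = "ordered")$y
}

# ---- ΔL40 generator calibration ------------------------------------------

#' Calibrated group distributions of excess loudness summation
#'
#' The synthetic cohort draws the latent ΔL40 (excess binaural broadband
#' loudness summation) from group-wise distributions calibrated to the
#' study conditions: skew-normal for the hearing-impaired groups with
#' New/Experienced mean 13.2 dB and Experimenter mean 8.1 dB, a shared
#' scale/shape solved numerically so the pooled hearing-impaired mixture
#' (New:Experienced:Experimenters weighted 88:72:20) has 2.5th/97.5th
#' percentiles −12.4/36.1 dB; and, for the normal-hearing group, a zero-mean
#' Gaussian whose 95th percentile is exactly the boundary value 17.2 dB
#' (sd = 17.2/qnorm(0.95)).
#'
#' The calibration is deterministic (no random numbers) and cached for the
#' session.
#'
#' @param mean_hapf,mean_experimenter Group means of ΔL40 in dB.
#' @param pooled_p Pooled hearing-impaired 2.5th/97.5th percentiles in dB.
#' @param pooled_weights Mixture weights of the HAPF groups (New +
#'   Experienced) versus the Experimenters.
#' @param nh_p95 95th percentile of the normal-hearing distribution in dB.
#' @return A list with elements `hapf` and `experimenter`
#'   (`xi`/`omega`/`alpha` skew-normal parameters), `nh` (`mean`/`sd`),
#'   `boundary` and the calibration residual.
#' @export
delta_l40_params <- function(mean_hapf = 13.2, mean_experimenter = 8.1,
                             pooled_p = c(-12.4, 36.1),
                             pooled_weights = c(160, 20) / 180,
                             nh_p95 = 17.2) {
  key <- paste0("dl40_", paste(c(mean_hapf, mean_experimenter, pooled_p,
                                 pooled_weights, nh_p95), collapse = "_"))
  if (!is.null(.loudsum_cache[[key]])) return(.loudsum_cache[[key]])
  xi_of <- function(mu, omega, alpha) {
    delta <- alpha / sqrt(1 + alpha^2)
    mu - omega * delta * sqrt(2 / pi)
  }
  objective <- function(par) {
    omega <- exp(par[1]); alpha <- par[2]
    xi <- c(xi_of(mean_hapf, omega, alpha),
            xi_of(mean_experimenter, omega, alpha))
    q <- sn_mixture_quantile(c(0.025, 0.975), xi, omega, alpha,
                             pooled_weights)
    sum((q - pooled_p)^2)
  }
  opt <- stats::optim(c(log(12), -1), objective,
                      control = list(reltol = 1e-12, maxit = 2000))
  omega <- exp(opt$par[1]); alpha <- opt$par[2]
  out <- list(
    hapf = list(xi = xi_of(mean_hapf, omega, alpha), omega = omega,
                alpha = alpha),
    experimenter = list(xi = xi_of(mean_experimenter, omega, alpha),
                        omega = omega, alpha = alpha),
    nh = list(mean = 0, sd = nh_p95 / stats::qnorm(0.95)),
    boundary = nh_p95,
    pooled_weights = pooled_weights,
    calibration_rmse = sqrt(opt$value / 2))
  .loudsum_cache[[key]] <- out
  out
}

#' Analytic moments and percentiles of the calibrated ΔL40 generator
#'
#' Computed from the distribution parameters, without sampling: group means,
#' pooled hearing-impaired mean/variance and 2.5/97.5 percentiles, and the
#' normal-hearing 95th percentile.
#'
#' @param params Output of [delta_l40_params()].
#' @return A named list.
#' @export
delta_l40_analytic <- function(params = delta_l40_params()) {
  h <- params$hapf; e <- params$experimenter
  w <- params$pooled_weights
  mu <- c(sn_mean(h$xi, h$omega, h$alpha),
          sn_mean(e$xi, e$omega, e$alpha))
  v <- c(sn_var(h$omega, h$alpha), sn_var(e$omega, e$alpha))
  pooled_mean <- sum(w * mu)
  pooled_var <- sum(w * (v + mu^2)) - pooled_mean^2
  q <- sn_mixture_quantile(c(0.025, 0.975), c(h$xi, e$xi), h$omega,
                           h$alpha, w)
  list(mean_hapf = mu[1], mean_experimenter = mu[2],
       pooled_mean = pooled_mean, pooled_sd = sqrt(pooled_var),
       pooled_p025 = q[1], pooled_p975 = q[2],
       nh_p95 = params$nh$mean + params$nh$sd * stats::qnorm(0.95))
}

#' Draw latent ΔL40 values for a participant group
#'
#' @param n Number of draws.
#' @param group One of `"New"`, `"Experienced"`, `"Experimenter"`, `"NH"`.
#'   New and Experienced share the HAPF distribution.
#' @param params Output of [delta_l40_params()].
#' @return Numeric vector of ΔL40 draws in dB. Uses R's global RNG.
#' @export
sample_delta_l40 <- function(n, group, params = delta_l40_params()) {
  group <- match.arg(group, c("New", "Experienced", "Experimenter", "NH"))
  if (group == "NH")
    return(stats::rnorm(n, params$nh$mean, params$nh$sd))
  p <- if (group == "Experimenter") params$experimenter else params$hapf
  rsn(n, p$xi, p$omega, p$alpha)
}

# ---- audiograms -----------------------------------------------------------

# N3-like moderately sloping anchor profile at the 11 audiometric
# frequencies (dB HL)
n3_anchor <- c(30, 35, 40, 45, 50, 55, 60, 65, 70, 70, 75)

#' Sampled audiogram for a participant group
#'
#' Hearing-impaired audiograms are drawn around an N3-like sloping anchor
#' (New users 5 dB better on average, matching their better PTA) with a
#' common intensity shift, a tilt component and smooth per-frequency
#' roughness, shared across ears up to a small interaural deviation, rounded
#' to 5 dB audiometric steps. Draws are rejected until the inclusion
#' criteria hold: better-ear PTA of at least 30 dB HL and an interaural PTA
#' difference of at most 15 dB. Normal-hearing audiograms are drawn near
#' 0 dB HL and rejected until thresholds exceed 15 dB HL at no more than two
#' frequencies per ear.
#'
#' @param group Participant group.
#' @param max_reject Rejection-sampling budget.
#' @return An [audiogram()]. Uses R's global RNG.
#' @export
sample_audiogram <- function(group, max_reject = 1000) {
  group <- match.arg(group, c("New", "Experienced", "Experimenter", "NH"))
  loct <- log2(audiometric_freqs / 1000)
  smooth3 <- function(x) stats::filter(c(x[1], x, x[length(x)]),
                                       rep(1 / 3, 3))[2:(length(x) + 1)]
  round5 <- function(x) pmin(120, pmax(-10, 5 * round(x / 5)))
  if (group == "NH") {
    for (i in seq_len(max_reject)) {
      draw <- function() round5(stats::rnorm(11, 2, 4))
      l <- draw(); r <- draw()
      if (sum(l > 15) <= 2 && sum(r > 15) <= 2)
        return(audiogram(l, r))
    }
    stop("rejection budget exhausted while sampling an NH audiogram")
  }
  anchor <- n3_anchor - if (group == "New") 5 else 0
  for (i in seq_len(max_reject)) {
    shift <- stats::rnorm(1, 0, 8)
    tilt <- stats::rnorm(1, 0, 2.5)
    rough <- as.numeric(smooth3(stats::rnorm(11, 0, 3)))
    base <- anchor + shift + tilt * loct + rough
    l <- round5(base + as.numeric(smooth3(stats::rnorm(11, 0, 2.5))))
    r <- round5(base + as.numeric(smooth3(stats::rnorm(11, 0, 2.5))))
    ag <- audiogram(l, r)
    if (min(pta(ag, "L"), pta(ag, "R")) >= 30 &&
        abs(pta(ag, "L") - pta(ag, "R")) <= 15)
      return(ag)
  }
  stop("rejection budget exhausted while sampling a hearing-impaired ",
       "audiogram")
}

# ---- covariates -----------------------------------------------------------

age_params <- list(New = c(70.9, 11.4), Experienced = c(72.7, 11.3),
                   Experimenter = c(75.9, 12.3), NH = c(21.5, 2))

# linear-Gaussian coupling: outcome = mu + slope*(delta - pooled mean) + e,
# slope and noise sd solved from the target R^2 against the pooled HI
# ΔL40 variance
coupling_coef <- function(target_r2, sigma_y, sigma_delta, sign = -1) {
  list(slope = sign * sigma_y * sqrt(target_r2) / sigma_delta,
       noise_sd = sigma_y * sqrt(1 - target_r2))
}

#' Sampled audiological covariates given a latent ΔL40
#'
#' Tone UCLs are Gaussian around 100 dB HL (clipped to \[80, 120\]), speech
#' UCLs carry a negative linear-Gaussian coupling to the latent ΔL40 with
#' coefficients solved from the target coefficients of determination
#' (minimum monaural speech UCL R² = 0.18, binaural speech UCL R² = 0.10,
#' PTA UCL R² = 0.06), the IHS total score a weak positive coupling
#' (R² = 0.03), and age is Gaussian with the group means/SDs (normal-hearing
#' listeners are young adults).
#'
#' @param group Participant group.
#' @param delta Latent ΔL40 in dB.
#' @param params Output of [delta_l40_params()].
#' @return A list with `tone_ucl_left`, `tone_ucl_right` (dB HL at
#'   0.5/1/2/4 kHz), `speech_ucl_left`, `speech_ucl_right`,
#'   `speech_ucl_binaural`, `ihs_score` and `age`. Uses R's global RNG.
#' @export
sample_covariates <- function(group, delta, params = delta_l40_params()) {
  an <- delta_l40_analytic(params)
  dc <- delta - an$pooled_mean
  sdd <- an$pooled_sd
  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

  cp <- coupling_coef(0.06, 7, sdd)
  ucl_base <- 100 + cp$slope * dc + stats::rnorm(1, 0, cp$noise_sd)
  tone_l <- clip(ucl_base + stats::rnorm(4, 0, 4), 80, 120)
  tone_r <- clip(ucl_base + stats::rnorm(4, 0, 4), 80, 120)

  cs <- coupling_coef(0.18, 10, sdd)
  speech_base <- 100 + cs$slope * dc + stats::rnorm(1, 0, cs$noise_sd)
  speech_l <- clip(speech_base + stats::rnorm(1, 0, 1.5), 75, 120)
  speech_r <- clip(speech_base + stats::rnorm(1, 0, 1.5), 75, 120)

  cb <- coupling_coef(0.10, 10, sdd)
  speech_bin <- clip(98 + cb$slope * dc + stats::rnorm(1, 0, cb$noise_sd),
                     75, 120)

  ci <- coupling_coef(0.03, 15, sdd, sign = +1)
  ihs <- round(clip(25 + ci$slope * dc + stats::rnorm(1, 0, ci$noise_sd),
                    0, 90))

  ap <- age_params[[group]]
  age <- if (group == "NH") round(stats::runif(1, 18, 25))
         else round(clip(stats::rnorm(1, ap[1], ap[2]), 18, 99))

  list(tone_ucl_left = stats::setNames(tone_l, pta_freqs),
       tone_ucl_right = stats::setNames(tone_r, pta_freqs),
       speech_ucl_left = speech_l, speech_ucl_right = speech_r,
       speech_ucl_binaural = speech_bin, ihs_score = ihs, age = age)
}

# ---- cohort ---------------------------------------------------------------

#' Generate a synthetic study cohort
#'
#' Draws a fully seeded cohort of participant records emulating the study
#' conditions: default group sizes 88 New, 72 Experienced, 20 Experimenters,
#' 20 normal-hearing. Each record carries the group label, age, audiogram,
#' tone and speech UCLs, IHS score, the latent ΔL40 drawn from the
#' calibrated group distribution, and a [virtual_listener()] whose aided
#' IFnoise binaural loudness function is the normal-hearing reference
#' shifted left by the latent ΔL40 (so its L40 is 82.3 − ΔL40 dB SPL),
#' with transition smoothing of 10 dB.
#'
#' @param sizes Named integer vector of group sizes.
#' @param seed Master seed.
#' @param noise_sd_cu Response noise of the virtual listeners in CU.
#' @param params Output of [delta_l40_params()].
#' @param refs A [default_references()] set.
#' @param smoothing Transition half-width of the listeners' true loudness
#'   functions in dB.
#' @return An object of class `"cohort"`: list of participant records plus
#'   generation metadata. `as.data.frame()` gives one row per participant.
#' @examples
#' coh <- generate_cohort(sizes = c(New = 5, Experienced = 5,
#'                                  Experimenter = 2, NH = 2), seed = 1)
#' head(as.data.frame(coh))
#' @export
generate_cohort <- function(sizes = c(New = 88, Experienced = 72,
                                      Experimenter = 20, NH = 20),
                            seed = 1, noise_sd_cu = 5,
                            params = delta_l40_params(),
                            refs = default_references(), smoothing = 10) {
  stopifnot(all(sizes >= 0),
            all(names(sizes) %in% c("New", "Experienced", "Experimenter",
                                    "NH")))
  set.seed(seed)
  records <- list()
  idx <- 0L
  for (group in names(sizes)) {
    for (k in seq_len(sizes[[group]])) {
      idx <- idx + 1L
      delta <- sample_delta_l40(1, group, params)
      ag <- sample_audiogram(group)
      cov <- sample_covariates(group, delta, params)
      fns <- lapply(refs$broadband, function(fn) {
        out <- shift_loudness_function(fn, delta)
        out$smoothing <- smoothing
        out
      })
      listener <- virtual_listener(fns, noise_sd_cu)
      records[[idx]] <- list(
        participant_id = sprintf("P%03d", idx), group = group,
        age = cov$age, audiogram = ag,
        tone_ucl_left = cov$tone_ucl_left,
        tone_ucl_right = cov$tone_ucl_right,
        speech_ucl_left = cov$speech_ucl_left,
        speech_ucl_right = cov$speech_ucl_right,
        speech_ucl_binaural = cov$speech_ucl_binaural,
        ihs_score = cov$ihs_score,
        latent_delta_l40 = delta, listener = listener)
    }
  }
  structure(list(records = records, sizes = sizes, seed = seed,
                 noise_sd_cu = noise_sd_cu, smoothing = smoothing),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$records), "participants (",
      paste(sprintf("%s %d", names(x$sizes), x$sizes), collapse = ", "),
      "), seed", x$seed, "\n")
  invisible(x)
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  do.call(rbind, lapply(x$records, function(r) {
    data.frame(participant_id = r$participant_id, group = r$group,
               age = r$age,
               pta = pta(r$audiogram),
               pta_left = pta(r$audiogram, "L"),
               pta_right = pta(r$audiogram, "R"),
               pta_ucl = mean(c(r$tone_ucl_left, r$tone_ucl_right)),
               speech_ucl_binaural = r$speech_ucl_binaural,
               speech_ucl_min_monaural = min(r$speech_ucl_left,
                                             r$speech_ucl_right),
               ihs_score = r$ihs_score,
               latent_delta_l40 = r$latent_delta_l40)
  }))
}
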