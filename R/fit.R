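#' Fit a categorical loudness function to scaling trials
#'
#' Weighted least-squares fit of the two-branch loudness-function model
#' (pivot 25 CU, smoothing off during fitting) to an adaptive-scaling trial
#' log. Saturated responses (0 or 50 CU) are treated as censored: they incur
#' a residual only when the unclipped model prediction falls on the wrong
#' side of the scale edge, and enter with weight 0.5. Optimization is
#' bounded (`l_cut` in \[0, 120\] dB, slopes in \[0.05, 5\] CU/dB,
#' L-BFGS-B), initialized by the line through the median level of the soft
#' responses (<= 25 CU) at their mean CU and the median level of the loud
#' responses (> 25 CU) at their mean CU.
#'
#' @param trials A data frame with columns `level_db_spl` and `response_cu`
#'   (e.g. from [run_adaptive_scaling()]), or the columns given via
#'   `level`/`response`.
#' @param level,response Optional numeric vectors used instead of `trials`.
#' @param censored_weight Weight of saturated responses (default 0.5).
#' @return An object of class `"loudness_fit"`: list with the fitted `fn`
#'   ([loudness_function()]), `coefficients`, the `trials`, `weights`,
#'   `fitted`, `residuals` and optimizer diagnostics. Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `residuals()`, `plot()` and
#'   `simulate()`.
#' @examples
#' fn <- loudness_function(70, 0.5, 1)
#' lv <- seq(40, 90, length.out = 11)
#' fit <- fit_loudness_function(level = lv, response = cu_at_level(fn, lv))
#' coef(fit)
#' @export
fit_loudness_function <- function(trials = NULL, level = NULL,
                                  response = NULL, censored_weight = 0.5) {
  if (!is.null(trials)) {
    stopifnot(is.data.frame(trials),
              all(c("level_db_spl", "response_cu") %in% names(trials)))
    level <- trials$level_db_spl
    response <- trials$response_cu
  }
  stopifnot(is.numeric(level), is.numeric(response),
            length(level) == length(response))
  if (length(level) < 6L)
    stop("unfittable data: need at least 6 trials, got ", length(level))
  saturated <- response <= 0 | response >= 50
  if (length(unique(response[!saturated])) < 3L)
    stop("unfittable data: need at least 3 distinct non-saturated responses")
  w <- ifelse(saturated, censored_weight, 1)

  obj <- function(par) {
    pred <- 25 + ifelse(level <= par[1], par[2], par[3]) * (level - par[1])
    pred <- pmin(50, pmax(0, pred))
    # censoring falls out of the clipped prediction: a response of 50 with
    # the prediction on the plateau leaves no residual, an under-prediction
    # is penalized
    sum(w * (pred - response)^2)
  }

  soft <- response <= 25
  if (any(soft) && any(!soft)) {
    x1 <- stats::median(level[soft]);  y1 <- mean(response[soft])
    x2 <- stats::median(level[!soft]); y2 <- mean(response[!soft])
    m0 <- (y2 - y1) / max(1e-6, x2 - x1)
    m0 <- min(5, max(0.05, m0))
    l0 <- x1 + (25 - y1) / m0
  } else {
    m0 <- 0.5
    l0 <- stats::median(level)
  }
  l0 <- min(120, max(0, l0))
  par0 <- c(l0, m0, m0)
  opt <- stats::optim(par0, obj, method = "L-BFGS-B",
                      lower = c(0, 0.05, 0.05), upper = c(120, 5, 5),
                      control = list(factr = 1e3, maxit = 500))
  fn <- loudness_function(opt$par[1], opt$par[2], opt$par[3], smoothing = 0)
  fitted <- cu_at_level(fn, level)
  structure(list(fn = fn,
                 coefficients = c(l_cut = opt$par[1], m_lo = opt$par[2],
                                  m_hi = opt$par[3]),
                 trials = data.frame(level_db_spl = level,
                                     response_cu = response),
                 weights = w, fitted = fitted,
                 residuals = response - fitted,
                 value = opt$value, convergence = opt$convergence),
            class = "loudness_fit")
}

#' @export
print.loudness_fit <- function(x, ...) {
  cat("Fitted categorical loudness function (weighted least squares)\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  L40: %.2f dB SPL   trials: %d   WSS: %.2f\n",
              l40(x$fn), nrow(x$trials), x$value))
  invisible(x)
}

#' @export
summary.loudness_fit <- function(object, ...) {
  res <- object$residuals
  out <- list(coefficients = object$coefficients,
              l40 = l40(object$fn),
              n_trials = nrow(object$trials),
              n_saturated = sum(object$weights < 1),
              rmse_cu = sqrt(mean(res^2)),
              convergence = object$convergence)
  class(out) <- "summary.loudness_fit"
  out
}

#' @export
print.summary.loudness_fit <- function(x, ...) {
  cat("Categorical loudness-function fit\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  L40 %.2f dB SPL; %d trials (%d saturated); residual RMSE %.2f CU\n",
              x$l40, x$n_trials, x$n_saturated, x$rmse_cu))
  if (x$convergence != 0) cat("  warning: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.loudness_fit <- function(object, ...) object$coefficients

#' @export
residuals.loudness_fit <- function(object, ...) object$residuals

#' @export
predict.loudness_fit <- function(object, newdata = NULL, ...) {
  lv <- if (is.null(newdata)) object$trials$level_db_spl
        else if (is.data.frame(newdata)) newdata$level_db_spl
        else newdata
  cu_at_level(object$fn, lv)
}

#' @export
plot.loudness_fit <- function(x, ...) {
  graphics::plot(x$trials$level_db_spl, x$trials$response_cu, pch = 1,
                 xlab = "Level [dB SPL]", ylab = "Loudness [CU]",
                 ylim = c(0, 50), ...)
  lv <- seq(min(x$trials$level_db_spl) - 5, max(x$trials$level_db_spl) + 5,
            length.out = 200)
  graphics::lines(lv, cu_at_level(x$fn, lv), col = "darkgreen", lwd = 2)
  invisible(x)
}

#' Simulate responses from a fitted loudness function
#'
#' Draws quantized categorical responses at the fitted trial levels (or at
#' `levels`), treating the fitted curve as the true function of a
#' [virtual_listener()] with the given response noise.
#'
#' @param object A `loudness_fit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed passed to [set.seed()].
#' @param levels Presentation levels (default: the fitted trial levels).
#' @param noise_sd_cu Response noise sd in CU.
#' @param ... Unused.
#' @return A data frame with one column per simulation.
#' @export
simulate.loudness_fit <- function(object, nsim = 1, seed = NULL,
                                  levels = NULL, noise_sd_cu = 5, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(levels)) levels <- object$trials$level_db_spl
  listener <- virtual_listener(list(IFnoise = object$fn), noise_sd_cu)
  out <- replicate(nsim, simulate_response(listener, "IFnoise", levels))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}
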