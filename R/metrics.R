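#' Excess binaural broadband loudness summation
#'
#' ΔL40 = L40ref − L40: the difference between the normal-hearing reference
#' level at 40 CU and an individual's level at 40 CU for the aided binaural
#' broadband stimulus. Positive values mean 40 CU is reached at lower input
#' levels than for the normal-hearing average, i.e. louder-than-normal
#' perception after narrowband loudness normalization.
#'
#' @param l40_ref Normal-hearing reference L40 in dB SPL (the packaged
#'   IFnoise binaural reference has 82.3 dB SPL).
#' @param l40 Individual L40 in dB SPL (vectorized).
#' @return ΔL40 in dB.
#' @examples
#' delta_l40(82.3, 69.3) # 13 dB: loud sounds reached 13 dB too early
#' @export
delta_l40 <- function(l40_ref, l40) {
  stopifnot(is.numeric(l40_ref), is.numeric(l40),
            all(is.finite(l40_ref)), all(is.finite(l40)))
  l40_ref - l40
}

#' Prevalence of excess loudness summation beyond a boundary
#'
#' Fraction of ΔL40 values strictly greater than the boundary (by default the
#' 95th percentile of the normal-hearing distribution, 17.2 dB).
#'
#' @param deltas Numeric vector of ΔL40 values in dB.
#' @param boundary Boundary value in dB.
#' @return Fraction in \[0, 1\].
#' @export
prevalence_excess <- function(deltas, boundary = 17.2) {
  if (!length(deltas)) stop("empty ΔL40 vector")
  stopifnot(is.numeric(deltas), all(is.finite(deltas)))
  mean(deltas > boundary)
}

#' Mean unsigned gain difference between two prescriptions
#'
#' Mean absolute insertion-gain difference over the comparison grid
#' (0.5/1/2/4 kHz by 50/65/80 dB SPL by both ears, 24 cells), with the
#' pre-defined meaningful-difference criterion: a mean unsigned difference
#' exceeding 5 dB.
#'
#' @param a,b [gain_table()]s covering the comparison grid.
#' @param frequencies,levels Comparison grid (defaults 500/1000/2000/4000 Hz
#'   and 50/65/80 dB SPL).
#' @param threshold Meaningful-difference threshold in dB (default 5).
#' @return A list with `mean_db`, `meaningful` (logical) and the per-cell
#'   difference array.
#' @export
mean_unsigned_gain_difference <- function(a, b,
                                          frequencies = c(500, 1000, 2000, 4000),
                                          levels = c(50, 65, 80),
                                          threshold = 5) {
  stopifnot(inherits(a, "gain_table"), inherits(b, "gain_table"))
  ears <- c("L", "R")
  sel <- function(x) {
    fi <- match(frequencies, x$frequencies)
    li <- match(levels, x$levels)
    ei <- match(ears, x$ears)
    if (any(is.na(fi)) || any(is.na(li)) || any(is.na(ei)))
      stop("gain table [", x$rule, "] does not cover the comparison grid")
    x$gains[fi, li, ei, drop = FALSE]
  }
  d <- sel(a) - sel(b)
  m <- mean(abs(d))
  list(mean_db = m, meaningful = m > threshold, difference_db = d)
}

#' Simple and multiple linear association with ΔL40-style outcomes
#'
#' `correlation_r2` returns the coefficient of determination and p-value of
#' an ordinary least-squares simple regression (equivalently squared Pearson
#' correlation); `adjusted_r2_multilinear` the adjusted R² of a multiple
#' regression.
#'
#' @param x Predictor vector / `X` data frame or matrix of predictors.
#' @param y Outcome vector.
#' @return `correlation_r2`: list with `r2` and `p`;
#'   `adjusted_r2_multilinear`: adjusted R².
#' @export
correlation_r2 <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input: correlation undefined")
  ct <- stats::cor.test(x, y)
  list(r2 = unname(ct$estimate^2), p = ct$p.value)
}

#' @rdname correlation_r2
#' @param X Data frame or matrix of predictors.
#' @export
adjusted_r2_multilinear <- function(X, y) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= ncol(X) + 2)
  if (any(vapply(X, function(col) stats::sd(col) == 0, logical(1))))
    stop("zero-variance (constant) predictor")
  fit <- stats::lm(y ~ ., data = cbind(X, y = y))
  summary(fit)$adj.r.squared
}

#' Pairwise Welch t-tests with Bonferroni correction
#'
#' Unpaired unequal-variance t-tests between all group pairs; p-values are
#' multiplied by the number of pairwise comparisons and capped at 1.
#'
#' @param values Numeric outcome vector.
#' @param groups Factor (or coercible) of group labels, >= 3 observations
#'   per compared group.
#' @return Data frame with columns `group1`, `group2`, `p_raw`,
#'   `p_bonferroni`.
#' @export
group_ttests <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  n_comp <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    p_raw = NA_real_)
  for (i in seq_len(n_comp)) {
    a <- values[groups == pairs[1, i]]
    b <- values[groups == pairs[2, i]]
    if (length(a) < 3 || length(b) < 3)
      stop("need at least 3 observations per compared group")
    out$p_raw[i] <- stats::t.test(a, b)$p.value
  }
  out$p_bonferroni <- pmin(1, out$p_raw * n_comp)
  out
}
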