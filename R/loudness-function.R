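#' Two-branch categorical loudness function
#'
#' Constructs the parametric model of a categorical loudness function used
#' throughout the package: loudness in categorical units (CU, 0--50) grows
#' linearly with level at a rate `m_lo` CU/dB below the pivot level `l_cut`
#' and at `m_hi` CU/dB above it, pivoting at 25 CU ("medium"). Evaluated CU
#' values are clipped to the response scale \[0, 50\]. An optional quadratic
#' Bezier transition of half-width `smoothing` dB around `l_cut` removes the
#' slope discontinuity (the transition is C1-continuous and preserves
#' monotonicity).
#'
#' @param l_cut Pivot level in dB (dB SPL for broadband/aided functions) at
#'   which the function passes through 25 CU.
#' @param m_lo Slope below `l_cut`, in CU/dB. Must be positive.
#' @param m_hi Slope above `l_cut`, in CU/dB. Must be positive.
#' @param smoothing Transition half-width in dB; `0` (default) disables
#'   smoothing so the function is piecewise linear with a kink at `l_cut`.
#' @return An object of class `"loudness_function"`.
#' @seealso [cu_at_level()], [level_at_cu()], [l40()]
#' @examples
#' fn <- loudness_function(l_cut = 70, m_lo = 0.5, m_hi = 1)
#' cu_at_level(fn, c(60, 70, 85))
#' level_at_cu(fn, 40)
#' @export
loudness_function <- function(l_cut, m_lo, m_hi, smoothing = 0) {
  stopifnot(is.numeric(l_cut), length(l_cut) == 1L, is.finite(l_cut),
            is.numeric(m_lo), length(m_lo) == 1L, is.finite(m_lo),
            is.numeric(m_hi), length(m_hi) == 1L, is.finite(m_hi),
            is.numeric(smoothing), length(smoothing) == 1L,
            is.finite(smoothing), smoothing >= 0)
  if (m_lo <= 0 || m_hi <= 0)
    stop("loudness-function slopes m_lo and m_hi must be positive (CU/dB)")
  structure(list(l_cut = l_cut, m_lo = m_lo, m_hi = m_hi,
                 smoothing = smoothing),
            class = "loudness_function")
}

#' @export
print.loudness_function <- function(x, ...) {
  cat("Categorical loudness function (two-branch linear, pivot 25 CU)\n")
  cat(sprintf("  l_cut: %.2f dB   m_lo: %.3f CU/dB   m_hi: %.3f CU/dB\n",
              x$l_cut, x$m_lo, x$m_hi))
  cat(sprintf("  smoothing half-width: %.1f dB   L40: %.2f dB\n",
              x$smoothing, l40(x)))
  invisible(x)
}

#' @export
plot.loudness_function <- function(x, from = x$l_cut - 50, to = x$l_cut + 35,
                                   ...) {
  lev <- seq(from, to, length.out = 300)
  graphics::plot(lev, cu_at_level(x, lev), type = "l",
                 xlab = "Level [dB]", ylab = "Loudness [CU]",
                 ylim = c(0, 50), ...)
  graphics::abline(h = c(25, 40), lty = 3, col = "grey50")
  invisible(x)
}

# Unclipped model value. Within the +/- h Bezier region the curve is the
# quadratic B(t) = (1-t)^2 c0 + 2 t (1-t) 25 + t^2 c1 with t linear in level,
# c0/c1 the linear-branch values at the region edges; B matches value and
# slope of both branches at the edges.
cu_raw <- function(fn, level) {
  h <- fn$smoothing
  lo <- 25 + fn$m_lo * (level - fn$l_cut)
  hi <- 25 + fn$m_hi * (level - fn$l_cut)
  out <- ifelse(level <= fn$l_cut, lo, hi)
  if (h > 0) {
    inside <- level > fn$l_cut - h & level < fn$l_cut + h
    if (any(inside)) {
      t <- (level[inside] - (fn$l_cut - h)) / (2 * h)
      c0 <- 25 - fn$m_lo * h
      c1 <- 25 + fn$m_hi * h
      out[inside] <- (1 - t)^2 * c0 + 2 * t * (1 - t) * 25 + t^2 * c1
    }
  }
  out
}

#' Evaluate a loudness function
#'
#' Returns the loudness in categorical units at the given level(s), clipped
#' to the categorical scale \[0, 50\].
#'
#' @param fn A [loudness_function()].
#' @param level Numeric vector of levels in dB.
#' @return Numeric vector of CU values in \[0, 50\]; monotone non-decreasing
#'   in `level`.
#' @export
cu_at_level <- function(fn, level) {
  stopifnot(inherits(fn, "loudness_function"), is.numeric(level))
  pmin(50, pmax(0, cu_raw(fn, level)))
}

#' Invert a loudness function
#'
#' Returns the level at which the loudness function reaches the given CU
#' value. Only CU values strictly inside the scale, in (0, 50), are
#' invertible; the clipped plateaus at 0 and 50 CU correspond to saturated
#' categories with no unique level and raise an error.
#'
#' @param fn A [loudness_function()].
#' @param cu Numeric vector of CU values, each strictly between 0 and 50.
#' @return Numeric vector of levels in dB, the exact inverse of
#'   [cu_at_level()] on the open CU range.
#' @export
level_at_cu <- function(fn, cu) {
  stopifnot(inherits(fn, "loudness_function"), is.numeric(cu))
  if (any(!is.finite(cu)) || any(cu <= 0) || any(cu >= 50))
    stop("cu must lie strictly within (0, 50); ",
         "0 and 50 CU are saturated categories and cannot be inverted")
  h <- fn$smoothing
  out <- ifelse(cu <= 25,
                fn$l_cut + (cu - 25) / fn$m_lo,
                fn$l_cut + (cu - 25) / fn$m_hi)
  if (h > 0) {
    c0 <- 25 - fn$m_lo * h
    c1 <- 25 + fn$m_hi * h
    inside <- cu > c0 & cu < c1
    if (any(inside)) {
      # invert the Bezier quadratic a t^2 + b t + (c0 - cu) = 0 on t in [0,1]
      a <- (fn$m_hi - fn$m_lo) * h
      b <- 2 * fn$m_lo * h
      cc <- c0 - cu[inside]
      t <- if (abs(a) < 1e-12) {
        -cc / b
      } else {
        (-b + sqrt(pmax(0, b^2 - 4 * a * cc))) / (2 * a)
      }
      out[inside] <- fn$l_cut - h + 2 * h * t
    }
  }
  out
}

#' Level at 40 categorical units
#'
#' The input level at which a loudness function reaches 40 CU (between
#' "loud" and "very loud"), the anchor point of the excess-summation
#' statistic ΔL40.
#'
#' @param fn A [loudness_function()].
#' @return Level in dB.
#' @export
l40 <- function(fn) level_at_cu(fn, 40)

#' Translate a loudness function along the level axis
#'
#' Shifting by a positive `shift` moves the curve toward lower levels, i.e.
#' every CU value is reached `shift` dB earlier. This is how excess binaural
#' broadband loudness summation is represented: a listener with excess
#' summation ΔL40 has the normal-hearing broadband reference function shifted
#' left by ΔL40 dB.
#'
#' @param fn A [loudness_function()].
#' @param shift Shift in dB toward lower levels.
#' @return A new `loudness_function`.
#' @export
shift_loudness_function <- function(fn, shift) {
  stopifnot(is.numeric(shift), length(shift) == 1L, is.finite(shift))
  loudness_function(fn$l_cut - shift, fn$m_lo, fn$m_hi, fn$smoothing)
}

# top of the unclipped curve: level where the upper branch reaches 50 CU
level_at_top <- function(fn) fn$l_cut + 25 / fn$m_hi

# bottom of the unclipped curve: level where the lower branch reaches 2.5 CU
# ("very soft" anchor)
level_at_soft <- function(fn) fn$l_cut - 22.5 / fn$m_lo
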