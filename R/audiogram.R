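#' Per-ear audiogram
#'
#' Air-conduction thresholds in dB HL at the 11 audiometric frequencies
#' 125 Hz--8 kHz for both ears, with optional bone-conduction thresholds at
#' 0.5/1/2/4 kHz.
#'
#' @param left,right Numeric vectors of length 11 with air-conduction
#'   thresholds in dB HL, ordered as `c(125, 250, 500, 750, 1000, 1500,
#'   2000, 3000, 4000, 6000, 8000)` Hz. Values must lie in \[-10, 120\].
#' @param bc_left,bc_right Optional numeric vectors of length 4 with
#'   bone-conduction thresholds at 0.5/1/2/4 kHz (NA allowed).
#' @return An object of class `"audiogram"`.
#' @examples
#' flat60 <- audiogram(rep(60, 11), rep(60, 11))
#' pta(flat60)
#' @export
audiogram <- function(left, right, bc_left = NULL, bc_right = NULL) {
  check_ac <- function(x, ear) {
    if (length(x) != length(audiometric_freqs))
      stop("ear ", ear, ": expected ", length(audiometric_freqs),
           " air-conduction thresholds, got ", length(x))
    if (any(!is.finite(x)) || any(x < -10) || any(x > 120))
      stop("ear ", ear, ": thresholds must lie in [-10, 120] dB HL")
    stats::setNames(as.numeric(x), audiometric_freqs)
  }
  check_bc <- function(x, ear) {
    if (is.null(x)) return(stats::setNames(rep(NA_real_, 4), pta_freqs))
    if (length(x) != 4L)
      stop("ear ", ear, ": expected 4 bone-conduction thresholds")
    stats::setNames(as.numeric(x), pta_freqs)
  }
  structure(list(left = check_ac(left, "L"), right = check_ac(right, "R"),
                 bc_left = check_bc(bc_left, "L"),
                 bc_right = check_bc(bc_right, "R")),
            class = "audiogram")
}

#' @export
print.audiogram <- function(x, ...) {
  cat("Audiogram (air conduction, dB HL)\n")
  m <- rbind(L = x$left, R = x$right)
  print(m)
  cat(sprintf("PTA: L %.1f, R %.1f, binaural %.1f dB HL\n",
              pta(x, "L"), pta(x, "R"), pta(x)))
  invisible(x)
}

#' @export
plot.audiogram <- function(x, ...) {
  f <- audiometric_freqs
  graphics::plot(f, x$left, log = "x", type = "b", pch = 4, col = "blue",
                 ylim = c(120, -10), xlab = "Frequency [Hz]",
                 ylab = "Threshold [dB HL]", ...)
  graphics::lines(f, x$right, type = "b", pch = 1, col = "red")
  graphics::legend("bottomleft", c("left", "right"), col = c("blue", "red"),
                   pch = c(4, 1), bty = "n")
  invisible(x)
}

#' Pure-tone average
#'
#' Unweighted mean of the air-conduction thresholds at 0.5, 1, 2 and 4 kHz,
#' for one ear or averaged over both.
#'
#' @param audiogram An [audiogram()].
#' @param ears `"both"` (default), `"L"` or `"R"`.
#' @return PTA in dB HL.
#' @export
pta <- function(audiogram, ears = c("both", "L", "R")) {
  stopifnot(inherits(audiogram, "audiogram"))
  ears <- match.arg(ears)
  sel <- as.character(pta_freqs)
  l <- audiogram$left[sel]
  r <- audiogram$right[sel]
  if (any(is.na(l)) || any(is.na(r)))
    stop("audiogram is missing thresholds at a PTA frequency (0.5/1/2/4 kHz)")
  switch(ears,
         L = mean(l),
         R = mean(r),
         both = mean(c(mean(l), mean(r))))
}
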