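#' Narrowband loudness-normalization gains
#'
#' First stage of the trueLOUDNESS-style prescription: monaural, per-ear
#' insertion gains that map each IFnoise third-octave band onto the level at
#' which the hearing-impaired narrowband loudness function (estimated from
#' the audiogram) produces the same categorical loudness as the
#' normal-hearing narrowband reference at the unamplified band level. For
#' each audiometric frequency `f` and broadband level `L`, the band level
#' `Lb(f, L)` is read from the packaged IFnoise spectrum, the target category
#' is `c = cu_at_level(NH_f, Lb)`, and the gain is
#' `g(f, L) = level_at_cu(HI_f, c) - Lb`. Gains are interpolated onto the
#' third-octave grid (log-frequency linear interpolation).
#'
#' If a target category saturates (0 or 50 CU, non-invertible) it is clamped
#' to \[2.5, 47.5\] and the gain is taken at the clamped category on both
#' curves; such cells are flagged in the returned table.
#'
#' @param audiogram An [audiogram()] with complete air-conduction thresholds.
#' @param refs A [default_references()] set.
#' @param levels Broadband input levels in dB SPL (default 50/65/80).
#' @return A [gain_table()] with rule `"narrowband-normalization"`.
#' @examples
#' g <- narrowband_normalization_gains(audiogram(rep(60, 11), rep(60, 11)))
#' gain_at(g, 1000, 65) # positive, and smaller than at 50 dB SPL input
#' @export
narrowband_normalization_gains <- function(audiogram,
                                           refs = default_references(),
                                           levels = c(50, 65, 80)) {
  stopifnot(inherits(audiogram, "audiogram"))
  grid <- third_octave_freqs
  gains <- array(0, dim = c(length(grid), length(levels), 2L))
  flags <- array(FALSE, dim = dim(gains))
  for (e in 1:2) {
    thr <- if (e == 1) audiogram$left else audiogram$right
    for (li in seq_along(levels)) {
      band <- levels[li] + refs$spectrum$rel_level_db
      lb <- stats::approx(log(refs$spectrum$band_hz), band,
                          xout = log(audiometric_freqs), rule = 2)$y
      g_audio <- numeric(length(audiometric_freqs))
      f_audio <- logical(length(audiometric_freqs))
      for (fi in seq_along(audiometric_freqs)) {
        nh <- nh_narrowband_reference(audiometric_freqs[fi], refs)
        hi <- estimate_narrowband_function(thr[fi], audiometric_freqs[fi],
                                           refs)
        cc <- cu_at_level(nh, lb[fi])
        if (cc <= 0 || cc >= 50) {
          cc <- min(47.5, max(2.5, cc))
          f_audio[fi] <- TRUE
          g_audio[fi] <- level_at_cu(hi, cc) - level_at_cu(nh, cc)
        } else {
          g_audio[fi] <- level_at_cu(hi, cc) - lb[fi]
        }
      }
      gains[, li, e] <- stats::approx(log(audiometric_freqs), g_audio,
                                      xout = log(grid), rule = 2)$y
      flagged_band <- stats::approx(log(audiometric_freqs),
                                    as.numeric(f_audio), xout = log(grid),
                                    rule = 2)$y > 0
      flags[, li, e] <- flagged_band
    }
  }
  gain_table(gains, grid, levels, c("L", "R"),
             rule = "narrowband-normalization", flags = flags)
}

#' Broadband loudness-normalization correction
#'
#' Third stage of the prescription: level-dependent additive gain offsets
#' derived from the measured aided broadband binaural loudness function. For
#' each broadband level `L`, the target category is the NH reference
#' loudness `c = cu_at_level(reference, L)` and the offset is
#' `level_at_cu(measured, c) - L`. A listener with excess binaural broadband
#' loudness summation (positive ΔL40, curve shifted toward lower levels)
#' therefore receives negative offsets, i.e. a gain reduction.
#'
#' @param measured Aided IFnoise binaural [loudness_function()] (typically a
#'   [fit_loudness_function()] fit).
#' @param reference NH IFnoise binaural reference [loudness_function()].
#' @param levels Broadband input levels in dB SPL.
#' @return An object of class `"broadband_correction"`: list with `levels`,
#'   `offset_db`, and `flagged` (saturated target categories, clamped to
#'   \[2.5, 47.5\] before inversion).
#' @export
broadband_correction <- function(measured,
                                 reference = default_references()$broadband$IFnoise,
                                 levels = c(50, 65, 80)) {
  if (inherits(measured, "loudness_fit")) measured <- measured$fn
  stopifnot(inherits(measured, "loudness_function"),
            inherits(reference, "loudness_function"))
  cc <- cu_at_level(reference, levels)
  flagged <- cc <= 0 | cc >= 50
  cc <- pmin(47.5, pmax(2.5, cc))
  offset <- level_at_cu(measured, cc) -
    ifelse(flagged, level_at_cu(reference, cc), levels)
  structure(list(levels = levels, offset_db = offset, flagged = flagged),
            class = "broadband_correction")
}

#' @export
print.broadband_correction <- function(x, ...) {
  cat("Broadband loudness-normalization correction (dB)\n")
  print(stats::setNames(round(x$offset_db, 2),
                        paste0(x$levels, " dB SPL")))
  if (any(x$flagged))
    cat("  (", sum(x$flagged), " level(s) extrapolated from a saturated ",
        "category)\n", sep = "")
  invisible(x)
}

#' trueLOUDNESS-style gain targets
#'
#' Combines the narrowband-normalization initial gains with the broadband
#' correction: the level-wise offset is added uniformly across frequency
#' (full bandwidth, no binaural difference), for both ears.
#'
#' @param initial [gain_table()] from [narrowband_normalization_gains()].
#' @param correction [broadband_correction()] at the same levels.
#' @return A [gain_table()] with rule `"trueLOUDNESS"`.
#' @export
trueloudness_gains <- function(initial, correction) {
  stopifnot(inherits(initial, "gain_table"),
            inherits(correction, "broadband_correction"),
            identical(as.numeric(initial$levels),
                      as.numeric(correction$levels)))
  gains <- initial$gains
  for (li in seq_along(initial$levels))
    gains[, li, ] <- gains[, li, ] + correction$offset_db[li]
  gain_table(gains, initial$frequencies, initial$levels, initial$ears,
             rule = "trueLOUDNESS", spectrum_id = initial$spectrum_id,
             flags = initial$flags)
}

#' Full trueLOUDNESS-style prescription for one listener
#'
#' Convenience wrapper running the three-step procedure: narrowband
#' normalization from the audiogram, broadband correction from the measured
#' aided IFnoise binaural loudness function, and their combination.
#'
#' @inheritParams narrowband_normalization_gains
#' @param measured Aided IFnoise binaural loudness function (or fit).
#' @return A [gain_table()] with rule `"trueLOUDNESS"`.
#' @export
prescribe_trueloudness <- function(audiogram, measured,
                                   refs = default_references(),
                                   levels = c(50, 65, 80)) {
  initial <- narrowband_normalization_gains(audiogram, refs, levels)
  corr <- broadband_correction(measured, refs$broadband$IFnoise, levels)
  trueloudness_gains(initial, corr)
}
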