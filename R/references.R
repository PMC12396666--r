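#' Audiometric frequencies used by the package
#'
#' The 11 air-conduction audiometric frequencies from 125 Hz to 8 kHz, the
#' four pure-tone-average (PTA) frequencies, and the third-octave comparison
#' grid used for insertion-gain tables.
#'
#' @name grids
#' @keywords internal
NULL

audiometric_freqs <- c(125, 250, 500, 750, 1000, 1500, 2000, 3000,
                       4000, 6000, 8000)
pta_freqs <- c(500, 1000, 2000, 4000)
third_octave_freqs <- c(125, 160, 200, 250, 315, 400, 500, 630, 800, 1000,
                        1250, 1600, 2000, 2500, 3150, 4000, 5000, 6300, 8000)

.loudsum_cache <- new.env(parent = emptyenv())

read_fixture_csv <- function(name) {
  path <- system.file("extdata", name, package = "loudsum")
  if (path == "") path <- file.path("inst", "extdata", name)
  utils::read.csv(path, comment.char = "#")
}

#' Normal-hearing loudness reference set
#'
#' Loads the packaged normal-hearing (NH) reference data: per-frequency
#' narrowband loudness-function parameters with the RETSPL-style HL-to-SPL
#' transfer table, per-stimulus binaural broadband loudness functions
#' (UEN5, UEN17, IFnoise), and the IFnoise third-octave band spectrum. The
#' packaged parameters are synthetic defaults (documented in the fixture
#' files); every coefficient of the audiogram-based estimation can be
#' overridden here.
#'
#' @param soft_offset_db dB by which the hearing-impaired "very soft"
#'   (2.5 CU) anchor sits above the audiometric threshold (default 2 dB).
#' @param top_recruitment Fraction of the threshold added to the NH 50-CU
#'   level to place the hearing-impaired top anchor (default 0.25, partial
#'   recruitment at the top of the scale).
#' @param min_dynamic_range_db Smallest admissible level distance between
#'   the 2.5-CU and 50-CU anchors of an estimated function (default 9.5 dB,
#'   equivalent to capping slopes at 5 CU/dB).
#' @return An object of class `"reference_set"` with elements `narrowband`
#'   (data frame), `broadband` (named list of [loudness_function()]s),
#'   `spectrum` (data frame with power-normalized relative band levels) and
#'   `coef`.
#' @examples
#' refs <- default_references()
#' level_at_cu(refs$broadband$IFnoise, 40) # 82.3 dB SPL
#' @export
default_references <- function(soft_offset_db = 2, top_recruitment = 0.25,
                               min_dynamic_range_db = 9.5) {
  key <- sprintf("refs_%g_%g_%g", soft_offset_db, top_recruitment,
                 min_dynamic_range_db)
  if (!is.null(.loudsum_cache[[key]])) return(.loudsum_cache[[key]])
  nb <- read_fixture_csv("nh_narrowband_references.csv")
  nb$frequency_hz <- as.numeric(nb$frequency_hz)
  stopifnot(identical(nb$frequency_hz, audiometric_freqs))
  # transfer-table consistency: NH very-soft anchor 2 dB above 0 dB HL
  soft <- nb$l_cut_db_spl - 22.5 / nb$m_lo_cu_per_db
  stopifnot(all(abs(soft - nb$hl_to_spl_offset_db - 2) < 1e-9))
  bb <- read_fixture_csv("nh_broadband_references.csv")
  broadband <- lapply(seq_len(nrow(bb)), function(i)
    loudness_function(bb$l_cut_db_spl[i], bb$m_lo_cu_per_db[i],
                      bb$m_hi_cu_per_db[i]))
  names(broadband) <- bb$stimulus_id
  sp <- read_fixture_csv("ifnoise_spectrum.csv")
  sp$band_hz <- as.numeric(sp$band_hz)
  stopifnot(identical(sp$band_hz, third_octave_freqs))
  sp$rel_level_db <- sp$rel_level_db -
    10 * log10(sum(10^(sp$rel_level_db / 10)))
  refs <- structure(list(
    narrowband = nb,
    broadband = broadband,
    spectrum = sp,
    coef = list(soft_offset_db = soft_offset_db,
                soft_cu = 2.5,
                top_recruitment = top_recruitment,
                min_dynamic_range_db = min_dynamic_range_db)),
    class = "reference_set")
  .loudsum_cache[[key]] <- refs
  refs
}

#' @export
print.reference_set <- function(x, ...) {
  cat("Normal-hearing loudness reference set\n")
  cat(sprintf("  narrowband functions at %d frequencies (%g-%g Hz)\n",
              nrow(x$narrowband), min(x$narrowband$frequency_hz),
              max(x$narrowband$frequency_hz)))
  cat(sprintf("  broadband stimuli: %s\n",
              paste(names(x$broadband), collapse = ", ")))
  cat(sprintf("  IFnoise L40ref: %.1f dB SPL\n",
              level_at_cu(x$broadband$IFnoise, 40)))
  invisible(x)
}

#' Normal-hearing narrowband reference function at a frequency
#'
#' @param frequency Audiometric frequency in Hz.
#' @param refs A [default_references()] set.
#' @param smoothing Transition half-width in dB passed to the returned
#'   function.
#' @return A [loudness_function()].
#' @export
nh_narrowband_reference <- function(frequency, refs = default_references(),
                                    smoothing = 0) {
  i <- match(frequency, refs$narrowband$frequency_hz)
  if (is.na(i))
    stop("unsupported frequency: ", frequency, " Hz (supported: ",
         paste(refs$narrowband$frequency_hz, collapse = ", "), ")")
  loudness_function(refs$narrowband$l_cut_db_spl[i],
                    refs$narrowband$m_lo_cu_per_db[i],
                    refs$narrowband$m_hi_cu_per_db[i], smoothing)
}

#' Convert hearing level to sound pressure level
#'
#' Applies the packaged RETSPL-style transfer table at an audiometric
#' frequency.
#'
#' @param level_hl Level(s) in dB HL.
#' @param frequency Audiometric frequency in Hz.
#' @param refs A [default_references()] set.
#' @return Level(s) in dB SPL.
#' @export
hl_to_spl <- function(level_hl, frequency, refs = default_references()) {
  i <- match(frequency, refs$narrowband$frequency_hz)
  if (is.na(i)) stop("unsupported frequency: ", frequency, " Hz")
  level_hl + refs$narrowband$hl_to_spl_offset_db[i]
}

#' Estimate a hearing-impaired narrowband loudness function from a threshold
#'
#' Two-anchor construction of the narrowband categorical loudness function of
#' a hearing-impaired ear from its audiometric threshold, exhibiting loudness
#' recruitment. Anchor A ("very soft", 2.5 CU) is placed `soft_offset_db`
#' (default 2 dB) above the threshold converted to dB SPL; anchor B (50 CU)
#' is placed at the NH function's 50-CU level plus `top_recruitment` times
#' the threshold (partial recruitment at the top of the scale). The pivot
#' level `l_cut` divides the anchor span in the same proportion as in the NH
#' reference, and the two slopes follow from the anchors. At 0 dB HL the
#' construction returns exactly the NH reference. The anchor span is floored
#' at `min_dynamic_range_db` so slopes stay bounded for profound losses.
#'
#' @param threshold Air-conduction threshold in dB HL, in \[-10, 120\].
#' @param frequency Audiometric frequency in Hz.
#' @param refs A [default_references()] set (carries all coefficients).
#' @param smoothing Transition half-width in dB for the returned function.
#' @return A [loudness_function()] on the dB SPL scale.
#' @examples
#' nh <- estimate_narrowband_function(0, 1000)
#' hi <- estimate_narrowband_function(60, 1000)
#' hi$m_lo > nh$m_lo # recruitment: steeper growth above threshold
#' @export
estimate_narrowband_function <- function(threshold, frequency,
                                         refs = default_references(),
                                         smoothing = 0) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (!is.finite(threshold) || threshold < -10 || threshold > 120)
    stop("threshold must lie in [-10, 120] dB HL")
  nh <- nh_narrowband_reference(frequency, refs)
  cf <- refs$coef
  l_a <- hl_to_spl(threshold + cf$soft_offset_db, frequency, refs)
  l_b <- level_at_top(nh) + cf$top_recruitment * threshold
  if (l_b - l_a < cf$min_dynamic_range_db)
    l_b <- l_a + cf$min_dynamic_range_db
  # pivot splits the anchor span in the NH proportion, so threshold 0
  # reproduces the NH reference exactly
  r <- (nh$l_cut - level_at_soft(nh)) / (level_at_top(nh) - level_at_soft(nh))
  l_cut <- l_a + r * (l_b - l_a)
  m_lo <- (25 - cf$soft_cu) / (l_cut - l_a)
  m_hi <- 25 / (l_b - l_cut)
  loudness_function(l_cut, m_lo, m_hi, smoothing)
}

#' IFnoise third-octave band levels at a broadband level
#'
#' @param overall_level_db Broadband overall level(s) in dB SPL.
#' @param refs A [default_references()] set.
#' @return A data frame with `band_hz` and one column `level_<L>` per
#'   requested overall level.
#' @export
ifnoise_band_levels <- function(overall_level_db,
                                refs = default_references()) {
  out <- data.frame(band_hz = refs$spectrum$band_hz)
  for (L in overall_level_db)
    out[[paste0("level_", L)]] <- L + refs$spectrum$rel_level_db
  out
}
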