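#' Insertion-gain table
#'
#' Per-ear insertion gains in dB on a frequency grid crossed with broadband
#' input levels (by default 50/65/80 dB SPL). Negative gains are permitted.
#' Cells whose derivation required extrapolation from a saturated loudness
#' category can be flagged.
#'
#' @param gains Numeric array of dimension `frequency x level x ear`, or a
#'   matrix `frequency x level` for a single ear.
#' @param frequencies Ascending frequency grid in Hz.
#' @param levels Broadband input levels in dB SPL.
#' @param ears Character vector of ear labels, subset of `c("L", "R")`.
#' @param rule Name of the prescription rule that produced the table.
#' @param spectrum_id Identifier of the input-signal spectrum.
#' @param flags Optional logical array of the same dimension as `gains`
#'   marking extrapolated (saturated) cells.
#' @return An object of class `"gain_table"`.
#' @export
gain_table <- function(gains, frequencies, levels, ears = c("L", "R"),
                       rule = "unnamed", spectrum_id = "IFnoise",
                       flags = NULL) {
  if (length(dim(gains)) == 2L) gains <- array(gains, dim = c(dim(gains), 1L))
  stopifnot(length(dim(gains)) == 3L,
            dim(gains)[1] == length(frequencies),
            dim(gains)[2] == length(levels),
            dim(gains)[3] == length(ears),
            !is.unsorted(frequencies, strictly = TRUE),
            all(is.finite(gains)))
  if (is.null(flags)) flags <- array(FALSE, dim = dim(gains))
  stopifnot(identical(dim(flags), dim(gains)))
  dn <- list(as.character(frequencies), as.character(levels), ears)
  dimnames(gains) <- dn
  dimnames(flags) <- dn
  structure(list(gains = gains, frequencies = as.numeric(frequencies),
                 levels = as.numeric(levels), ears = ears, rule = rule,
                 spectrum_id = spectrum_id, flags = flags),
            class = "gain_table")
}

#' @export
print.gain_table <- function(x, ...) {
  cat(sprintf("Insertion-gain table [%s], spectrum %s\n", x$rule,
              x$spectrum_id))
  cat(sprintf("  %d frequencies x %d levels x %d ear(s); %d flagged cell(s)\n",
              length(x$frequencies), length(x$levels), length(x$ears),
              sum(x$flags)))
  for (e in x$ears) {
    cat("  ear ", e, " (rows: Hz, cols: dB SPL input):\n", sep = "")
    print(round(x$gains[, , e], 1))
  }
  invisible(x)
}

#' Look up gains in a gain table
#'
#' @param x A [gain_table()].
#' @param frequency,level,ear Scalars selecting a cell (vectors allowed for
#'   `frequency`).
#' @return Gain(s) in dB.
#' @export
gain_at <- function(x, frequency, level, ear = "L") {
  stopifnot(inherits(x, "gain_table"))
  fi <- match(frequency, x$frequencies)
  li <- match(level, x$levels)
  ei <- match(ear, x$ears)
  if (any(is.na(fi)) || is.na(li) || is.na(ei))
    stop("requested cell not on the gain-table grid")
  x$gains[fi, li, ei]
}

#' Write / read a gain table as CSV
#'
#' Long format with columns `participant_id, ear, rule, frequency_hz,
#' level_db_spl, insertion_gain_db`. Values round-trip bit-exactly (gains are
#' serialized with 17 significant digits).
#'
#' @param x A [gain_table()].
#' @param path File path.
#' @param participant_id Identifier written to / filtered from the CSV.
#' @return `write_gain_table` returns `path` invisibly; `read_gain_table`
#'   returns a [gain_table()].
#' @export
write_gain_table <- function(x, path, participant_id = "unknown") {
  stopifnot(inherits(x, "gain_table"))
  grid <- expand.grid(frequency_hz = x$frequencies,
                      level_db_spl = x$levels, ear = x$ears,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- data.frame(participant_id = participant_id, ear = grid$ear,
                   rule = x$rule, frequency_hz = grid$frequency_hz,
                   level_db_spl = grid$level_db_spl,
                   insertion_gain_db = formatC(as.vector(x$gains),
                                               digits = 17, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gain_table
#' @export
read_gain_table <- function(path, participant_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "ear", "rule", "frequency_hz",
                "level_db_spl", "insertion_gain_db")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("gain-table CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.null(participant_id)) df <- df[df$participant_id == participant_id, ]
  if (!nrow(df)) stop("gain-table CSV contains no matching rows")
  bad_ear <- !df$ear %in% c("L", "R")
  if (any(bad_ear))
    stop("invalid ear label in row(s) ",
         paste(utils::head(which(bad_ear), 5), collapse = ", "),
         " (must be L or R)")
  freqs <- sort(unique(df$frequency_hz))
  levels <- sort(unique(df$level_db_spl))
  ears <- sort(unique(df$ear))
  gains <- array(NA_real_, dim = c(length(freqs), length(levels),
                                   length(ears)))
  fi <- match(df$frequency_hz, freqs)
  li <- match(df$level_db_spl, levels)
  ei <- match(df$ear, ears)
  gains[cbind(fi, li, ei)] <- as.numeric(df$insertion_gain_db)
  if (any(is.na(gains)))
    stop("gain-table CSV grid is incomplete: missing frequency/level/ear ",
         "combinations")
  gain_table(gains, freqs, levels, ears, rule = df$rule[1])
}

#' Generic threshold-based stand-in gain rule
#'
#' A deliberately simple, clearly labelled stand-in prescription used only to
#' exercise the comparison pipeline where external prescriptive procedures
#' (whose engines are closed tools) would otherwise be imported from CSV.
#' Gain is proportional to the threshold with a compressive level dependence,
#' floored at 0 dB, and zero wherever the threshold indicates no loss:
#' `g(T, L) = max(0, 0.5 T - 10 (L - 65)/15)` for `T > 0`, else 0.
#'
#' @param audiogram An [audiogram()].
#' @param levels Broadband input levels in dB SPL (default 50/65/80).
#' @param refs A [default_references()] set (for the frequency grid).
#' @return A [gain_table()] on the third-octave grid, rule `"stand-in"`.
#' @export
stand_in_rule <- function(audiogram, levels = c(50, 65, 80),
                          refs = default_references()) {
  stopifnot(inherits(audiogram, "audiogram"))
  grid <- third_octave_freqs
  thr <- function(ear) {
    stats::approx(log(audiometric_freqs), ear, xout = log(grid),
                  rule = 2)$y
  }
  gains <- array(0, dim = c(length(grid), length(levels), 2L))
  for (e in 1:2) {
    t_grid <- thr(if (e == 1) audiogram$left else audiogram$right)
    for (li in seq_along(levels)) {
      g <- 0.5 * t_grid - 10 * (levels[li] - 65) / 15
      g[t_grid <= 0] <- 0
      gains[, li, e] <- pmax(0, g)
    }
  }
  gain_table(gains, grid, levels, c("L", "R"), rule = "stand-in")
}

#' Compression ratio between two broadband input levels
#'
#' `CR = dLin / (dLin + G(high) - G(low))` with `dLin = level_high -
#' level_low`. `CR = 1` for level-independent gain, `CR > 1` for compressive
#' gain, `0 < CR < 1` for expansion. Non-positive or non-finite ratios
#' (gain decreasing faster than the input level rises) are returned as-is
#' with the `"invalid"` attribute set; a zero denominator yields `Inf`,
#' flagged, not an error.
#'
#' @param gain_low,gain_high Gains in dB at the low/high input level
#'   (vectorized).
#' @param level_low,level_high Broadband input levels in dB SPL,
#'   `level_high > level_low`.
#' @return Numeric vector of compression ratios with a logical attribute
#'   `invalid` marking non-finite or non-positive (degenerate) values.
#' @examples
#' compression_ratio(30, 15, 50, 80) # 2: halved output dynamics
#' @export
compression_ratio <- function(gain_low, gain_high, level_low, level_high) {
  stopifnot(length(level_low) == 1L, length(level_high) == 1L,
            level_high > level_low)
  dlin <- level_high - level_low
  denom <- dlin + gain_high - gain_low
  cr <- ifelse(denom == 0, Inf, dlin / denom)
  attr(cr, "invalid") <- !is.finite(cr) | cr <= 0
  cr
}
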