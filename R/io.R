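#' Write / read audiograms as CSV
#'
#' Long schema: `participant_id, ear, frequency_hz, ac_threshold_db_hl,
#' bc_threshold_db_hl` (bone conduction may be blank). Unknown extra columns
#' are tolerated with a warning; invalid ear labels or an incomplete
#' frequency grid raise errors naming the offending rows/columns.
#'
#' @param audiograms Named list of [audiogram()]s (names are participant
#'   ids), or a [generate_cohort()] cohort.
#' @param path File path.
#' @return `write_audiograms` returns `path` invisibly; `read_audiograms` a
#'   named list of [audiogram()]s.
#' @export
write_audiograms <- function(audiograms, path) {
  if (inherits(audiograms, "cohort")) {
    ids <- vapply(audiograms$records, `[[`, character(1), "participant_id")
    audiograms <- stats::setNames(lapply(audiograms$records, `[[`,
                                         "audiogram"), ids)
  }
  rows <- lapply(names(audiograms), function(id) {
    ag <- audiograms[[id]]
    bc <- function(e) {
      full <- stats::setNames(rep(NA_real_, 11), audiometric_freqs)
      full[as.character(pta_freqs)] <- e
      full
    }
    data.frame(participant_id = id,
               ear = rep(c("L", "R"), each = 11),
               frequency_hz = rep(audiometric_freqs, 2),
               ac_threshold_db_hl = c(ag$left, ag$right),
               bc_threshold_db_hl = c(bc(ag$bc_left), bc(ag$bc_right)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_audiograms
#' @export
read_audiograms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "ear", "frequency_hz",
                "ac_threshold_db_hl", "bc_threshold_db_hl")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("audiogram CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), required)
  if (length(extra))
    warning("audiogram CSV has unknown column(s), ignored: ",
            paste(extra, collapse = ", "))
  bad_ear <- !df$ear %in% c("L", "R")
  if (any(bad_ear))
    stop("invalid ear label in row(s) ",
         paste(utils::head(which(bad_ear), 5), collapse = ", "),
         " (must be L or R)")
  out <- list()
  for (id in unique(df$participant_id)) {
    sub <- df[df$participant_id == id, ]
    get_ear <- function(e) {
      s <- sub[sub$ear == e, ]
      ac <- s$ac_threshold_db_hl[match(audiometric_freqs, s$frequency_hz)]
      if (any(is.na(ac)))
        stop("participant ", id, " ear ", e, ": missing air-conduction ",
             "threshold at ",
             paste(audiometric_freqs[is.na(ac)], collapse = ", "), " Hz")
      bc <- s$bc_threshold_db_hl[match(pta_freqs, s$frequency_hz)]
      list(ac = ac, bc = bc)
    }
    l <- get_ear("L"); r <- get_ear("R")
    out[[id]] <- audiogram(l$ac, r$ac, l$bc, r$bc)
  }
  out
}

#' Write / read scaling trial logs as CSV
#'
#' Schema: `participant_id, stimulus_id, trial_index, level_db_spl,
#' response_cu`.
#'
#' @param trials Data frame of trials including `participant_id` (bind the
#'   output of [run_adaptive_scaling()] per participant).
#' @param path File path.
#' @return `write_trials` returns `path` invisibly; `read_trials` the data
#'   frame.
#' @export
write_trials <- function(trials, path) {
  required <- c("participant_id", "stimulus_id", "trial_index",
                "level_db_spl", "response_cu")
  stopifnot(all(required %in% names(trials)))
  utils::write.csv(trials[required], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "stimulus_id", "trial_index",
                "level_db_spl", "response_cu")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("trial CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(!df$response_cu %in% seq(0, 50, 5)))
    stop("trial CSV contains responses outside the 11 categories 0,5,...,50")
  df
}
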