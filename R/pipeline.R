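#' Pipeline configuration
#'
#' All knobs of the end-to-end simulation pipeline: master seed, group
#' sizes, scaling-procedure settings, the gain-comparison grid (0.5/1/2/4
#' kHz at 50/65/80 dB SPL), the pre-defined meaningful-difference threshold
#' (5 dB mean unsigned gain difference) and the excess-summation boundary
#' (17.2 dB, the normal-hearing 95th percentile).
#'
#' @param seed Master seed for the whole pipeline.
#' @param sizes Named group sizes.
#' @param scaling A [scaling_config()].
#' @param comparison_frequencies,comparison_levels Gain-comparison grid.
#' @param meaningful_difference_db Threshold on the mean unsigned gain
#'   difference.
#' @param boundary_db Excess-summation boundary.
#' @return A named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1,
                            sizes = c(New = 88, Experienced = 72,
                                      Experimenter = 20, NH = 20),
                            scaling = scaling_config(),
                            comparison_frequencies = c(500, 1000, 2000, 4000),
                            comparison_levels = c(50, 65, 80),
                            meaningful_difference_db = 5,
                            boundary_db = 17.2) {
  stopifnot(meaningful_difference_db > 0, boundary_db > 0,
            length(comparison_frequencies) >= 1,
            length(comparison_levels) >= 1)
  structure(list(seed = seed, sizes = sizes, scaling = scaling,
                 comparison_frequencies = comparison_frequencies,
                 comparison_levels = comparison_levels,
                 meaningful_difference_db = meaningful_difference_db,
                 boundary_db = boundary_db),
            class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [pipeline_config()] (`sizes` and
#'   `scaling` as nested maps).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("seed", "comparison_frequencies", "comparison_levels",
              "meaningful_difference_db", "boundary_db"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$sizes)) args$sizes <- unlist(y$sizes)
  if (!is.null(y$scaling)) args$scaling <- do.call(scaling_config, y$scaling)
  do.call(pipeline_config, args)
}

#' Run the full simulation and analysis pipeline
#'
#' Executes simulate-cohort, aided loudness scaling, loudness-function
#' fitting, gain prescription (trueLOUDNESS-style and the labelled stand-in
#' threshold rule), and the cohort analysis: measured ΔL40 per participant,
#' group means, prevalence of excess summation beyond the boundary,
#' compression-ratio distributions, prescription-difference statistics and
#' predictor correlations. All randomness is governed by `config$seed`;
#' identical configurations produce byte-identical outputs.
#'
#' @param config A [pipeline_config()] (or a path to a YAML file).
#' @param out_dir Optional output directory; when given, writes
#'   `participants.csv`, `audiograms.csv`, `trials.csv`, `gains.csv` and
#'   `summary.json` there.
#' @return A list with `results` (one row per participant) and `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  refs <- default_references()
  l40ref <- level_at_cu(refs$broadband$IFnoise, 40)

  cohort <- tryCatch(
    generate_cohort(config$sizes, config$seed,
                    noise_sd_cu = config$scaling$noise_sd_cu),
    error = function(e) stop("stage simulate-cohort: ",
                             conditionMessage(e)))
  results <- as.data.frame(cohort)

  trials_all <- list()
  gains_all <- list()
  measured <- numeric(length(cohort$records))
  mud <- numeric(length(cohort$records))
  cr_rows <- list()
  for (i in seq_along(cohort$records)) {
    rec <- cohort$records[[i]]
    trials <- tryCatch(
      run_adaptive_scaling(rec$listener, "IFnoise", config$scaling),
      error = function(e) stop("stage scale [", rec$participant_id, "]: ",
                               conditionMessage(e)))
    trials$participant_id <- rec$participant_id
    trials_all[[i]] <- trials
    fit <- tryCatch(fit_loudness_function(trials),
                    error = function(e) stop("stage fit [",
                                             rec$participant_id, "]: ",
                                             conditionMessage(e)))
    measured[i] <- delta_l40(l40ref, l40(fit$fn))
    tl <- tryCatch(prescribe_trueloudness(rec$audiogram, fit, refs,
                                          config$comparison_levels),
                   error = function(e) stop("stage prescribe [",
                                            rec$participant_id, "]: ",
                                            conditionMessage(e)))
    si <- stand_in_rule(rec$audiogram, config$comparison_levels, refs)
    gains_all[[i]] <- list(id = rec$participant_id, trueloudness = tl,
                           stand_in = si)
    mud[i] <- mean_unsigned_gain_difference(
      tl, si, config$comparison_frequencies, config$comparison_levels,
      config$meaningful_difference_db)$mean_db
    for (f in config$comparison_frequencies) {
      lo <- min(config$comparison_levels); hi <- max(config$comparison_levels)
      for (ear in c("L", "R")) {
        cr <- compression_ratio(gain_at(tl, f, lo, ear),
                                gain_at(tl, f, hi, ear), lo, hi)
        cr_rows[[length(cr_rows) + 1L]] <-
          data.frame(participant_id = rec$participant_id, group = rec$group,
                     frequency_hz = f, ear = ear, cr = as.numeric(cr),
                     invalid = attr(cr, "invalid"))
      }
    }
  }
  results$measured_delta_l40 <- measured
  results$mean_gain_difference_db <- mud
  results$meaningful_difference <-
    mud > config$meaningful_difference_db
  cr_table <- do.call(rbind, cr_rows)

  groups <- c("New", "Experienced", "Experimenter", "NH")
  group_stats <- lapply(groups, function(g) {
    sub <- results[results$group == g, ]
    if (!nrow(sub))
      return(list(n = 0L, present = FALSE))
    list(n = nrow(sub), present = TRUE,
         mean_measured_delta_l40 = mean(sub$measured_delta_l40),
         mean_latent_delta_l40 = mean(sub$latent_delta_l40),
         prevalence_excess = prevalence_excess(sub$measured_delta_l40,
                                               config$boundary_db),
         meaningful_difference_rate = mean(sub$meaningful_difference))
  })
  names(group_stats) <- groups

  hi <- results[results$group != "NH", ]
  predictors <- c("pta", "pta_ucl", "speech_ucl_binaural",
                  "speech_ucl_min_monaural", "ihs_score", "age")
  correlations <- if (nrow(hi) >= 10) {
    lapply(stats::setNames(predictors, predictors), function(p)
      correlation_r2(hi[[p]], hi$measured_delta_l40))
  } else NULL
  adj_r2 <- if (nrow(hi) >= 20)
    adjusted_r2_multilinear(hi[predictors], hi$measured_delta_l40)
  else NULL

  valid_cr <- cr_table$cr[!cr_table$invalid]
  summary <- list(
    seed = config$seed,
    n_participants = nrow(results),
    l40ref_db_spl = l40ref,
    boundary_db = config$boundary_db,
    group_stats = group_stats,
    pooled_hi = if (nrow(hi)) list(
      n = nrow(hi),
      mean_measured_delta_l40 = mean(hi$measured_delta_l40),
      p025_measured_delta_l40 =
        unname(stats::quantile(hi$measured_delta_l40, 0.025)),
      p975_measured_delta_l40 =
        unname(stats::quantile(hi$measured_delta_l40, 0.975)),
      prevalence_excess = prevalence_excess(hi$measured_delta_l40,
                                            config$boundary_db)) else NULL,
    rmse_delta_l40_recovery =
      sqrt(mean((results$measured_delta_l40 - results$latent_delta_l40)^2)),
    compression_ratio = list(
      n_valid = length(valid_cr), n_invalid = sum(cr_table$invalid),
      median = if (length(valid_cr)) stats::median(valid_cr) else NULL,
      q25 = if (length(valid_cr))
        unname(stats::quantile(valid_cr, 0.25)) else NULL,
      q75 = if (length(valid_cr))
        unname(stats::quantile(valid_cr, 0.75)) else NULL),
    gain_difference = list(
      mean_db = mean(mud),
      meaningful_rate = mean(results$meaningful_difference),
      cumulative = {
        br <- c(0, 2.5, 5, 7.5, 10, 15, 20, Inf)
        as.list(stats::setNames(
          as.numeric(cumsum(table(cut(mud, br)))) / length(mud),
          paste0("le_", br[-1])))
      }),
    correlations = correlations,
    adjusted_r2_multilinear = adj_r2)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(out_dir, "participants.csv"),
                     row.names = FALSE)
    write_audiograms(cohort, file.path(out_dir, "audiograms.csv"))
    write_trials(do.call(rbind, trials_all),
                 file.path(out_dir, "trials.csv"))
    gd <- do.call(rbind, lapply(gains_all, function(g) {
      rbind(gain_table_long(g$trueloudness, g$id),
            gain_table_long(g$stand_in, g$id))
    }))
    utils::write.csv(gd, file.path(out_dir, "gains.csv"),
                     row.names = FALSE)
    utils::write.csv(cr_table, file.path(out_dir, "compression_ratios.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, null = "null",
                         pretty = TRUE)
  }
  list(results = results, summary = summary, cr_table = cr_table)
}

gain_table_long <- function(x, participant_id) {
  grid <- expand.grid(frequency_hz = x$frequencies,
                      level_db_spl = x$levels, ear = x$ears,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(participant_id = participant_id, ear = grid$ear,
             rule = x$rule, frequency_hz = grid$frequency_hz,
             level_db_spl = grid$level_db_spl,
             insertion_gain_db = as.vector(x$gains))
}
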