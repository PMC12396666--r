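test_that("calibration closure: analytic generator moments hit the targets", {
  an <- delta_l40_analytic()
  expect_equal(an$mean_hapf, 13.2, tolerance = 1e-9)
  expect_equal(an$mean_experimenter, 8.1, tolerance = 1e-9)
  expect_equal(an$nh_p95, 17.2, tolerance = 1e-12)
  expect_equal(an$pooled_p025, -12.4, tolerance = 1e-3)
  expect_equal(an$pooled_p975, 36.1, tolerance = 1e-3)
  # and against an independent numerical CDF of the mixture
  p <- delta_l40_params()
  w <- p$pooled_weights
  cdf <- function(q) w[1] * sn_cdf_numeric(q, p$hapf$xi, p$hapf$omega,
                                           p$hapf$alpha) +
    w[2] * sn_cdf_numeric(q, p$experimenter$xi, p$experimenter$omega,
                          p$experimenter$alpha)
  expect_equal(cdf(-12.4), 0.025, tolerance = 1e-3)
  expect_equal(cdf(36.1), 0.975, tolerance = 1e-3)
})

test_that("sampled group means and percentiles match the calibration", {
  set.seed(123)
  ex <- sample_delta_l40(100000, "Experienced")
  expect_lt(abs(mean(ex) - 13.2), 0.2)
  expt <- sample_delta_l40(100000, "Experimenter")
  expect_lt(abs(mean(expt) - 8.1), 0.2)
  pooled <- c(sample_delta_l40(88000, "New"),
              sample_delta_l40(72000, "Experienced"),
              sample_delta_l40(20000, "Experimenter"))
  expect_lt(abs(quantile(pooled, 0.975) - 36.1), 1)
  expect_lt(abs(quantile(pooled, 0.025) - (-12.4)), 1)
  nh <- sample_delta_l40(100000, "NH")
  expect_lt(abs(quantile(nh, 0.95) - 17.2), 0.3)
})

test_that("hearing-impaired audiograms satisfy the inclusion criteria", {
  set.seed(42)
  for (i in 1:300) {
    g <- sample(c("New", "Experienced", "Experimenter"), 1)
    ag <- sample_audiogram(g)
    expect_gte(min(pta(ag, "L"), pta(ag, "R")), 30)
    expect_lte(abs(pta(ag, "L") - pta(ag, "R")), 15)
  }
})

test_that("audiogram draws centre on the sloping anchor profile", {
  set.seed(7)
  draws <- replicate(1000, sample_audiogram("Experienced")$left)
  anchor <- c(30, 35, 40, 45, 50, 55, 60, 65, 70, 70, 75)
  expect_true(all(abs(rowMeans(draws) - anchor) < 5))
})

test_that("normal-hearing audiograms stay near 0 dB HL", {
  set.seed(9)
  for (i in 1:50) {
    ag <- sample_audiogram("NH")
    expect_lte(sum(ag$left > 15), 2)
    expect_lte(sum(ag$right > 15), 2)
  }
})

test_that("audiogram sampling is reproducible under a fixed seed", {
  set.seed(31); a <- sample_audiogram("New")
  set.seed(31); b <- sample_audiogram("New")
  expect_identical(a, b)
})

test_that("covariates: UCL clipping and calibrated speech-UCL coupling", {
  set.seed(55)
  n <- 10000
  deltas <- c(sample_delta_l40(round(n * 88 / 180), "New"),
              sample_delta_l40(round(n * 72 / 180), "Experienced"),
              sample_delta_l40(round(n * 20 / 180), "Experimenter"))
  covs <- lapply(deltas, function(d) sample_covariates("Experienced", d))
  tone <- unlist(lapply(covs, function(x) c(x$tone_ucl_left,
                                            x$tone_ucl_right)))
  expect_true(all(tone >= 80 & tone <= 120))
  expect_lt(abs(mean(tone) - 100), 1)
  min_mono <- vapply(covs, function(x)
    min(x$speech_ucl_left, x$speech_ucl_right), numeric(1))
  r2 <- correlation_r2(min_mono, deltas)$r2
  expect_lt(abs(r2 - 0.18), 0.05)
  bin <- vapply(covs, `[[`, numeric(1), "speech_ucl_binaural")
  expect_lt(abs(correlation_r2(bin, deltas)$r2 - 0.10), 0.05)
  ihs <- vapply(covs, `[[`, numeric(1), "ihs_score")
  expect_lt(abs(correlation_r2(ihs, deltas)$r2 - 0.03), 0.03)
})

test_that("group ages match the configured means", {
  set.seed(14)
  ages <- replicate(10000, sample_covariates("New", 10)$age)
  expect_lt(abs(mean(ages) - 70.9), 0.4)
})

test_that("cohort generation: sizes, listener construction, determinism", {
  coh <- generate_cohort(sizes = c(New = 6, Experienced = 5,
                                   Experimenter = 3, NH = 3), seed = 17)
  expect_length(coh$records, 17)
  df <- as.data.frame(coh)
  expect_equal(as.numeric(table(df$group)[c("New", "Experienced",
                                            "Experimenter", "NH")]),
               c(6, 5, 3, 3))
  # aided IFnoise function: L40 = 82.3 - latent dL40
  for (r in coh$records[c(1, 8, 15)]) {
    expect_equal(l40(r$listener$functions$IFnoise),
                 82.3 - r$latent_delta_l40, tolerance = 1e-9)
  }
  # byte-identical cohort CSV under the same seed
  coh2 <- generate_cohort(sizes = c(New = 6, Experienced = 5,
                                    Experimenter = 3, NH = 3), seed = 17)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_audiograms(coh, f1)
  write_audiograms(coh2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("default cohort sizes reflect the study composition", {
  frm <- formals(generate_cohort)
  sizes <- eval(frm$sizes)
  expect_equal(unname(sizes), c(88, 72, 20, 20))
  expect_equal(sum(sizes), 200)
})
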