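test_that("a normal-hearing audiogram prescribes zero narrowband gains", {
  g <- narrowband_normalization_gains(flat_audiogram(0))
  expect_lt(max(abs(g$gains)), 0.1)
  # low-frequency bands at 50 dB SPL overall fall below the NH audible
  # range, so saturation flags are allowed -- but never at mid frequencies
  # and 65/80 dB SPL
  expect_false(any(g$flags[as.character(c(500, 1000, 2000, 4000)),
                           c("65", "80"), ]))
})

test_that("recruitment makes narrowband-normalization gains compressive", {
  g <- narrowband_normalization_gains(flat_audiogram(60))
  for (ear in c("L", "R")) {
    g50 <- g$gains[, "50", ear]
    g65 <- g$gains[, "65", ear]
    g80 <- g$gains[, "80", ear]
    expect_true(all(g65 < g50))
    expect_true(all(g80 < g65))
  }
  # monaural symmetry for a symmetric audiogram
  expect_equal(g$gains[, , "L"], g$gains[, , "R"])
})

test_that("narrowband gains match an independent two-curve grid search", {
  refs <- default_references()
  g <- narrowband_normalization_gains(flat_audiogram(60), refs)
  lb <- 65 + refs$spectrum$rel_level_db[refs$spectrum$band_hz == 1000]
  nh <- nh_narrowband_reference(1000, refs)
  hi <- estimate_narrowband_function(60, 1000, refs)
  target_cu <- cu_at_level(nh, lb)
  oracle_gain <- grid_search_level(hi, target_cu) - lb
  expect_lt(abs(gain_at(g, 1000, 65) - oracle_gain), 0.1)
})

test_that("broadband correction: identity, translation law, slope change", {
  refs <- default_references()
  ref <- refs$broadband$IFnoise
  expect_equal(broadband_correction(ref, ref)$offset_db, c(0, 0, 0))
  # translation by d toward lower levels gives offsets -d at every level
  for (d in c(-8, 5, 10, 20)) {
    shifted <- shift_loudness_function(ref, d)
    expect_equal(broadband_correction(shifted, ref)$offset_db,
                 rep(-d, 3), tolerance = 1e-9)
  }
  # doubled upper slope: compare against 0.01-dB grid-search inversion
  steep <- loudness_function(ref$l_cut, ref$m_lo, 2 * ref$m_hi)
  bc <- broadband_correction(steep, ref)
  for (i in seq_along(bc$levels)) {
    cu <- cu_at_level(ref, bc$levels[i])
    expect_lt(abs(bc$offset_db[i] -
                    (grid_search_level(steep, cu) - bc$levels[i])), 0.011)
  }
})

test_that("trueLOUDNESS gains add the correction uniformly over frequency", {
  initial <- narrowband_normalization_gains(flat_audiogram(50))
  zero <- broadband_correction(default_references()$broadband$IFnoise)
  expect_equal(trueloudness_gains(initial, zero)$gains, initial$gains,
               ignore_attr = TRUE)
  corr <- structure(list(levels = c(50, 65, 80),
                         offset_db = c(-10, -12, -15),
                         flagged = rep(FALSE, 3)),
                    class = "broadband_correction")
  final <- trueloudness_gains(initial, corr)
  expect_equal(final$gains[, "65", ], initial$gains[, "65", ] - 12)
  expect_equal(final$gains[, "50", ], initial$gains[, "50", ] - 10)
  expect_equal(final$gains[, "80", ], initial$gains[, "80", ] - 15)
})

test_that("excess summation reduces final gains", {
  refs <- default_references()
  ag <- flat_audiogram(60)
  initial <- narrowband_normalization_gains(ag, refs)
  measured <- shift_loudness_function(refs$broadband$IFnoise, 20) # dL40 = 20
  final <- prescribe_trueloudness(ag, measured, refs)
  expect_true(all(final$gains[, "80", ] < initial$gains[, "80", ]))
})

test_that("final gains are non-increasing in the listener's excess summation", {
  refs <- default_references()
  ag <- flat_audiogram(55)
  deltas <- seq(-15, 35, by = 5)
  tabs <- lapply(deltas, function(d)
    prescribe_trueloudness(
      ag, shift_loudness_function(refs$broadband$IFnoise, d), refs))
  for (i in seq_len(length(tabs) - 1)) {
    expect_true(all(tabs[[i + 1]]$gains <= tabs[[i]]$gains + 1e-9))
  }
})

test_that("no excess summation means near-zero broadband correction end-to-end", {
  # virtual listener whose aided broadband function IS the NH reference
  # (perfect narrowband normalization, no excess summation), measured
  # noise-free through the adaptive procedure
  set.seed(12)
  refs <- default_references()
  li <- virtual_listener(list(IFnoise = refs$broadband$IFnoise), 0)
  # dense coverage so the 5-CU response quantization does not dominate
  fit <- fit_loudness_function(
    run_adaptive_scaling(li, "IFnoise", scaling_config(trial_budget = 44)))
  bc <- broadband_correction(fit, refs$broadband$IFnoise)
  expect_true(all(abs(bc$offset_db) <= 1))
})

test_that("compression ratio follows the gain-difference formula", {
  expect_equal(as.numeric(compression_ratio(30, 15, 50, 80)), 2)
  expect_equal(as.numeric(compression_ratio(12, 12, 50, 80)), 1)
  cr <- compression_ratio(0, 5, 50, 80)
  expect_equal(as.numeric(cr), 30 / 35)
  expect_false(attr(cr, "invalid"))     # expansion is valid, just < 1
  # zero denominator: flagged infinite result, not an exception
  cr0 <- compression_ratio(30, 0, 50, 80)
  expect_true(is.infinite(cr0[1]))
  expect_true(attr(cr0, "invalid"))
  # negative denominator: degenerate, flagged
  crn <- compression_ratio(40, 0, 50, 80)
  expect_true(attr(crn, "invalid"))
})

test_that("compression ratio agrees with direct formula on random pairs", {
  set.seed(99)
  gl <- runif(1000, -10, 50)
  gh <- runif(1000, -10, 50)
  cr <- compression_ratio(gl, gh, 50, 80)
  direct <- (80 - 50) / ((80 - 50) + gh - gl)
  ok <- is.finite(direct)
  expect_equal(as.numeric(cr)[ok], direct[ok], tolerance = 1e-9)
})
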