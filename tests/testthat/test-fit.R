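test_that("noise-free responses at exact categories are recovered exactly", {
  fn <- loudness_function(70, 0.5, 1)
  lv <- c(category_levels(fn), level_at_cu(fn, c(10, 40)))
  li <- virtual_listener(list(IFnoise = fn), 0)
  resp <- simulate_response(li, "IFnoise", lv)
  fit <- fit_loudness_function(level = lv, response = resp)
  expect_equal(unname(coef(fit)), c(70, 0.5, 1), tolerance = 1e-3)
  expect_equal(l40(fit$fn), 85, tolerance = 1e-3)
})

test_that("degenerate trial logs are rejected", {
  expect_error(fit_loudness_function(level = rep(100, 10),
                                     response = rep(50, 10)),
               "distinct non-saturated")
  expect_error(fit_loudness_function(level = c(60, 70, 80),
                                     response = c(10, 25, 40)),
               "at least 6 trials")
  expect_error(fit_loudness_function(level = seq(60, 90, 5),
                                     response = rep(25, 7)),
               "distinct")
})

test_that("L40 recovery RMSE stays within 3 dB at the default settings", {
  # Monte-Carlo oracle: 200 virtual listeners drawn from the calibrated
  # cohort conditions, noise 5 CU, 22 trials
  set.seed(2024)
  refs <- default_references()
  err <- replicate(200, {
    d <- sample_delta_l40(1, "Experienced")
    f <- shift_loudness_function(refs$broadband$IFnoise, d)
    f$smoothing <- 10
    li <- virtual_listener(list(IFnoise = f), 5)
    fit <- fit_loudness_function(run_adaptive_scaling(li, "IFnoise"))
    l40(fit$fn) - l40(f)
  })
  expect_lt(sqrt(mean(err^2)), 3)
})

test_that("estimated L40 is unbiased within 1 dB across the usable range", {
  set.seed(31)
  refs <- default_references()
  true_l40 <- runif(500, 55, 100)
  err <- vapply(true_l40, function(L) {
    f <- shift_loudness_function(refs$broadband$IFnoise, 82.3 - L)
    f$smoothing <- 10
    li <- virtual_listener(list(IFnoise = f), 5)
    fit <- fit_loudness_function(run_adaptive_scaling(li, "IFnoise"))
    l40(fit$fn) - L
  }, numeric(1))
  expect_lt(abs(mean(err)), 1)
})

test_that("fit quality degrades monotonically with response noise", {
  refs <- default_references()
  f <- refs$broadband$IFnoise
  f$smoothing <- 10
  rmse_at <- function(sd, seeds) {
    err <- vapply(seeds, function(s) {
      set.seed(s)
      li <- virtual_listener(list(IFnoise = f), sd)
      fit <- fit_loudness_function(run_adaptive_scaling(li, "IFnoise"))
      l40(fit$fn) - 82.3
    }, numeric(1))
    sqrt(mean(err^2))
  }
  seeds <- 1:150
  expect_gte(rmse_at(8, seeds), rmse_at(3, seeds))
})

test_that("loudness_fit supports the standard model methods", {
  set.seed(8)
  fn <- loudness_function(68, 0.6, 1.1, smoothing = 10)
  li <- virtual_listener(list(IFnoise = fn), 5)
  tr <- run_adaptive_scaling(li, "IFnoise")
  fit <- fit_loudness_function(tr)
  expect_s3_class(fit, "loudness_fit")
  expect_named(coef(fit), c("l_cut", "m_lo", "m_hi"))
  expect_length(residuals(fit), nrow(tr))
  expect_equal(predict(fit, newdata = tr$level_db_spl),
               cu_at_level(fit$fn, tr$level_db_spl))
  s <- summary(fit)
  expect_s3_class(s, "summary.loudness_fit")
  expect_output(print(fit), "L40")
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(nrow(tr), 3))
  expect_true(all(unlist(sim) %in% seq(0, 50, 5)))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
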