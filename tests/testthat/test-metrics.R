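test_that("excess summation is the reference-minus-individual L40 difference", {
  expect_equal(delta_l40(82.3, 69.3), 13.0)
  expect_equal(delta_l40(82.3, 82.3), 0)
  expect_equal(delta_l40(80.0, 100.0), -20.0)
  # antisymmetry
  set.seed(2)
  a <- runif(50, 40, 110); b <- runif(50, 40, 110)
  expect_equal(delta_l40(a, b), -delta_l40(b, a))
})

test_that("PTA averages 0.5/1/2/4 kHz thresholds over the requested ears", {
  ag <- audiogram(c(20, 25, 40, 42, 45, 48, 50, 52, 55, 60, 65),
                  c(20, 25, 40, 42, 45, 48, 50, 52, 55, 60, 65))
  expect_equal(pta(ag, "L"), mean(c(40, 45, 50, 55)))
  expect_equal(pta(ag), pta(ag, "L"))         # identical ears
  ag2 <- audiogram(rep(40, 11), rep(60, 11))
  expect_equal(pta(ag2), 50)
  broken <- ag
  broken$left["500"] <- NA
  expect_error(pta(broken), "PTA frequency")
})

test_that("prevalence counts strict exceedances of the boundary", {
  expect_equal(prevalence_excess(c(10, 20), 17.2), 0.5)
  expect_equal(prevalence_excess(rep(17.2, 5), 17.2), 0)
  expect_error(prevalence_excess(numeric(0)), "empty")
  # equals 1 - empirical CDF at the boundary, invariant to relabeling
  set.seed(10)
  x <- rnorm(500, 10, 8)
  expect_equal(prevalence_excess(x, 17.2),
               1 - stats::ecdf(x)(17.2))
  expect_equal(prevalence_excess(sample(x), 17.2),
               prevalence_excess(x, 17.2))
})

test_that("sampled prevalence matches the generator's analytic exceedance", {
  set.seed(77)
  p <- delta_l40_params()
  draws <- sample_delta_l40(10000, "Experienced", p)
  analytic <- 1 - sn_cdf_numeric(17.2, p$hapf$xi, p$hapf$omega, p$hapf$alpha)
  mc_se <- sqrt(analytic * (1 - analytic) / 10000)
  expect_lt(abs(prevalence_excess(draws, 17.2) - analytic), 4 * mc_se)
})

test_that("mean unsigned gain difference and the 5-dB criterion", {
  set.seed(6)
  a <- random_gain_table()
  expect_equal(mean_unsigned_gain_difference(a, a)$mean_db, 0)
  expect_false(mean_unsigned_gain_difference(a, a)$meaningful)
  b <- a; b$gains <- a$gains + 6
  d <- mean_unsigned_gain_difference(a, b)
  expect_equal(d$mean_db, 6)
  expect_true(d$meaningful)
  # unsigned averaging: +4 on half the cells, -4 on the rest -> mean 4
  cc <- a
  signs <- rep(c(4, -4), length.out = length(a$gains))
  cc$gains <- a$gains + array(signs, dim = dim(a$gains))
  d2 <- mean_unsigned_gain_difference(a, cc)
  expect_equal(d2$mean_db, 4)
  expect_false(d2$meaningful)
  # grid mismatch
  small <- gain_table(matrix(0, 2, 3), c(500, 1000), c(50, 65, 80),
                      ears = "L")
  expect_error(mean_unsigned_gain_difference(a, small), "grid")
})

test_that("mean unsigned gain difference is a metric on the fixed grid", {
  set.seed(8)
  for (i in 1:10) {
    a <- random_gain_table(); b <- random_gain_table()
    cc <- random_gain_table()
    dab <- mean_unsigned_gain_difference(a, b)$mean_db
    dba <- mean_unsigned_gain_difference(b, a)$mean_db
    dac <- mean_unsigned_gain_difference(a, cc)$mean_db
    dcb <- mean_unsigned_gain_difference(cc, b)$mean_db
    expect_gte(dab, 0)
    expect_equal(dab, dba)
    expect_lte(dab, dac + dcb + 1e-12)
  }
  a <- random_gain_table()
  expect_equal(mean_unsigned_gain_difference(a, a)$mean_db, 0)
})

test_that("simple and multiple regression statistics", {
  x <- 1:20
  expect_equal(correlation_r2(x, 2 * x)$r2, 1)
  set.seed(15)
  xn <- rnorm(10000); yn <- rnorm(10000)
  expect_lt(correlation_r2(xn, yn)$r2, 0.01)
  expect_error(correlation_r2(rep(1, 10), rnorm(10)), "zero-variance")
  X <- data.frame(a = rnorm(100), b = rnorm(100))
  y <- 2 * X$a - X$b + rnorm(100, 0, 0.1)
  expect_gt(adjusted_r2_multilinear(X, y), 0.95)
  expect_error(adjusted_r2_multilinear(data.frame(a = rep(1, 50)),
                                       rnorm(50)), "constant")
})

test_that("pairwise Welch tests hold their type-I error and Bonferroni cap", {
  set.seed(20)
  rej <- replicate(1000, {
    g <- rep(c("a", "b"), each = 15)
    v <- rnorm(30)
    group_ttests(v, g)$p_raw < 0.05
  })
  expect_lt(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 1000) + 0.005)
  # three groups: 3 comparisons, p multiplied by 3 and capped at 1
  set.seed(21)
  v <- rnorm(60)
  g <- rep(c("a", "b", "c"), each = 20)
  tt <- group_ttests(v, g)
  expect_equal(nrow(tt), 3)
  expect_equal(tt$p_bonferroni, pmin(1, tt$p_raw * 3))
  expect_error(group_ttests(rnorm(4), c("a", "a", "b", "b")),
               "at least 3")
})
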