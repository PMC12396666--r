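# shared fixtures and independent oracles

# brute-force inversion of a loudness function on a 0.01-dB grid;
# independent of the analytic level_at_cu branches
grid_search_level <- function(fn, cu, from = -50, to = 200, by = 0.01) {
  lv <- seq(from, to, by = by)
  lv[which.min(abs(cu_at_level(fn, lv) - cu))]
}

random_loudness_function <- function(smoothing = 0) {
  loudness_function(l_cut = stats::runif(1, 40, 90),
                    m_lo = stats::runif(1, 0.2, 1.5),
                    m_hi = stats::runif(1, 0.3, 2.5),
                    smoothing = smoothing)
}

# levels whose true CU values are exact response categories, so noise-free
# quantization is lossless
category_levels <- function(fn, cats = seq(5, 45, by = 5)) {
  level_at_cu(fn, cats)
}

random_gain_table <- function(rule = "random") {
  g <- array(stats::rnorm(4 * 3 * 2, 15, 8), dim = c(4, 3, 2))
  gain_table(g, c(500, 1000, 2000, 4000), c(50, 65, 80), c("L", "R"),
             rule = rule)
}

flat_audiogram <- function(db) audiogram(rep(db, 11), rep(db, 11))

# numeric CDF of the package's skew-normal, independent of its sampler
sn_cdf_numeric <- function(q, xi, omega, alpha) {
  stats::integrate(function(x) {
    z <- (x - xi) / omega
    2 / omega * stats::dnorm(z) * stats::pnorm(alpha * z)
  }, -Inf, q, rel.tol = 1e-10)$value
}
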