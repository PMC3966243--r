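test_that("calibrated reference distributions carry the published moments", {
  spec <- table1_spec()
  expect_equal(spec$k_d1$mean, 1.13)
  expect_equal(spec$k_d1$sd, 0.056)
  expect_equal(spec$k_d2$mean, 1.27)
  expect_equal(spec$beta$mean, 0.50)
  expect_equal(spec$gamma_c$mean, 0.0032)
  expect_equal(spec$m1$mean, 270)
  expect_equal(spec$k_v2$sd, 1.41)
  pri <- table1_priors()
  expect_equal(c(pri$k_d1$lo, pri$k_d1$hi), c(1.025, 1.175))
  expect_equal(c(pri$gamma_c$lo, pri$gamma_c$hi), c(0.00005, 0.0025))
})

test_that("truncated-normal draws stay positive and match truncated moments", {
  # analytic truncated-normal mean as the oracle
  tn_mean <- function(mu, sd, lo = 0) {
    a <- (lo - mu) / sd
    mu + sd * dnorm(a) / (1 - pnorm(a))
  }
  set.seed(11)
  d <- dist_truncnorm(0.0032, 0.00117)
  x <- dist_sample(d, 1e5)
  expect_true(all(x > 0))
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - tn_mean(0.0032, 0.00117)), 3 * se)
  # positivity barely binds for k_d1: truncated mean ~ raw mean
  expect_equal(dist_mean(dist_truncnorm(1.13, 0.056)), 1.13,
               tolerance = 1e-10)
})

test_that("cdf and inverse cdf are mutually inverse", {
  set.seed(12)
  ds <- list(dist_uniform(2, 5),
             dist_truncnorm(1.2, 0.3, lo = 0.5, hi = 2),
             fit_kernel(rnorm(200, 10, 2), support = c(0, Inf)))
  for (d in ds) {
    x <- dist_quantile(d, seq(0.05, 0.95, by = 0.05))
    expect_equal(dist_quantile(d, dist_cdf(d, x)), x, tolerance = 1e-6)
  }
})

test_that("kernel fits converge to the generating distribution", {
  set.seed(13)
  u <- runif(5000)
  d <- fit_kernel(u, support = c(0, 1))
  x <- seq(0.02, 0.98, by = 0.01)
  expect_lt(max(abs(dist_cdf(d, x) - punif(x))), 0.05)
  # density symmetric about the sample mean for a symmetric sample
  ds <- fit_kernel(c(1, 2, 3, 1.5, 2.5), support = c(-Inf, Inf))
  expect_equal(dist_quantile(ds, 0.5), 2, tolerance = ds$bw)
})

test_that("inverse-cdf sampling reproduces the fitted cdf", {
  set.seed(14)
  d <- fit_kernel(rgamma(500, 4, 2), support = c(0, Inf))
  x <- dist_sample(d, 1e5)
  ks <- suppressWarnings(ks.test(x, function(q) dist_cdf(d, q)))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("degenerate samples collapse to a point mass with a warning", {
  expect_warning(d <- fit_kernel(rep(2, 10)), "degenerate")
  expect_equal(dist_sample(d, 5), rep(2, 5))
})

test_that("gland sampling is seed-reproducible and respects the layout", {
  spec <- table1_spec()
  g1 <- sample_gland(spec, seed = 42)
  g2 <- sample_gland(spec, seed = 42)
  expect_identical(g1$params, g2$params)
  expect_equal(nrow(g1$params), 40)
  expect_equal(sum(g1$params$sensitive), 20)
  expect_true(all(g1$params$gamma_c < g1$params$beta))
  expect_true(all(g1$params$beta <= 1))
  expect_equal(unique(g1$params$k_deg), 0.02)
  # single-pair comparison model
  g3 <- sample_gland(table1_spec(n_pairs = 1), seed = 1)
  expect_equal(nrow(g3$params), 2)
})

test_that("pooled sensitive set points recover the population mean", {
  set.seed(15)
  spec <- table1_spec()
  kd <- unlist(lapply(1:250, function(i) {
    g <- sample_gland(spec)
    g$params$k_d[g$params$sensitive]
  }))
  se <- sd(kd) / sqrt(length(kd))
  expect_lt(abs(mean(kd) - 1.13), 3 * se)
})

test_that("mean gland and ordering warnings behave", {
  g <- mean_gland(table1_spec(), n_pairs = 1)
  expect_equal(nrow(g$params), 2)
  expect_equal(g$params$k_d, c(1.13, 1.27), tolerance = 1e-6)
  expect_warning(
    gland_spec(dist_uniform(1, 2), dist_uniform(1, 2),
               dist_uniform(0.2, 0.8), dist_uniform(1e-4, 1e-3),
               dist_uniform(100, 200), dist_uniform(100, 200),
               k_d1 = dist_uniform(1.3, 1.4), k_d2 = dist_uniform(1.0, 1.1)),
    "k_d1")
})
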