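make_obs <- function(times = c(0, 10, 60), means = c(50, 80, 60),
                     sds = c(5, 8, 6),
                     phases = c("baseline", "peak", "hypo")) {
  observation_set(times, means, sds, phases)
}

test_that("z-scores match hand arithmetic", {
  g <- pair_gland()
  sim <- simulate_gland(g, clamp_protocol("A"), dt = 0.5, t_end = 65)
  obs <- make_obs(means = serum_at(sim, c(0, 10, 60)))
  expect_equal(phase_zscores(sim, obs), c(0, 0, 0))
  obs2 <- make_obs(means = serum_at(sim, c(0, 10, 60)) - c(5, 8, 6))
  expect_equal(phase_zscores(sim, obs2), c(1, 1, 1))
  obs3 <- observation_set(c(0, 10, 60), c(10, 20, 30), c(2, 4, 5),
                          c("baseline", "peak", "hypo"))
  y <- serum_at(sim, c(0, 10, 60))
  expect_equal(phase_zscores(sim, obs3),
               (y - c(10, 20, 30)) / c(2, 4, 5))
  short <- simulate_gland(g, clamp_protocol("A"), dt = 0.5, t_end = 30)
  expect_error(phase_zscores(short, obs), "range")
})

test_that("retention gate is inclusive at the boundary and monotone", {
  expect_true(retain_models(c(0, 0, 0)))
  expect_false(retain_models(c(0.2, 1.6)))
  expect_true(retain_models(c(1.5, -1.5)))  # inclusive boundary
  set.seed(20)
  zs <- replicate(50, rnorm(6), simplify = FALSE)
  k15 <- retain_models(zs, 1.5)
  k20 <- retain_models(zs, 2.0)
  expect_true(all(k20[k15]))  # widening the gate never drops a model
})

test_that("stopping rule applies both conditions", {
  expect_true(calibration_converged(rep(0, 5)))
  expect_false(calibration_converged(c(0.8, 0, 0, 0)))    # max rule
  expect_false(calibration_converged(rep(0.4, 6)))        # mean-square 0.16
  expect_true(calibration_converged(rep(0.25, 6)))        # 0.0625 < 0.1
  # pairwise-product reading differs for sign-mixed scores
  z <- c(0.5, -0.5, 0.5, -0.5)
  expect_false(calibration_converged(z, rule = "mean-square"))
  expect_true(calibration_converged(z, rule = "pairwise-product"))
})

test_that("observation sets validate and round-trip through CSV", {
  expect_error(observation_set(1, 10, 0, "hypo"), "SD")
  expect_error(observation_set(1, 10, 1, "weird"), "phase")
  obs <- make_obs()
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations_csv(obs, path)
  obs2 <- read_observations_csv(path)
  expect_equal(as.data.frame(obs2), as.data.frame(obs))
})

test_that("calibration runs deterministically and records iterations", {
  truth <- sample_gland(table1_priors(), seed = 7)
  st <- synthetic_study(truth = truth, noise_sd = 0.15, seed = 33)
  obs <- generate_observations(st)
  run <- function() calibrate(table1_priors(), obs, n_models = 80,
                              max_iter = 2, dt = 1, seed = 99)
  r1 <- run(); r2 <- run()
  expect_equal(r1$history, r2$history)
  expect_equal(dist_mean(r1$spec$k_d1), dist_mean(r2$spec$k_d1))
  expect_true(all(r1$history$n_retained >= 1))
  expect_true(all(r1$history$n_retained <= r1$history$n_sampled))
  expect_s3_class(r1$spec$k_d1, "param_dist")
  expect_equal(r1$spec$k_d1$kind, "kernel")
})

test_that("calibration rejects empty ensembles and impossible targets", {
  obs <- make_obs()
  expect_error(calibrate(table1_priors(), obs, n_models = 0), "n_models")
  # absurd targets: nothing within 1.5 SD -> collapse error with diagnostics
  bad <- observation_set(c(0, 10, 60), c(1e6, 1e6, 1e6), c(1, 1, 1),
                         c("baseline", "peak", "hypo"))
  expect_error(calibrate(table1_priors(), bad, n_models = 10, max_iter = 1,
                         dt = 1, seed = 1),
               "no models retained")
})

test_that("self-consistent targets converge with non-empty retention", {
  # targets equal to the priors' own ensemble-mean output (with a 15%
  # relative SD): the candidate ensemble centres on these values
  pr <- clamp_protocol("A")
  lay <- observation_layout("A")
  set.seed(46)
  Y <- sapply(1:30, function(i)
    serum_at(simulate_gland(sample_gland(table1_priors()), pr,
                            dt = 1, t_end = 172), lay$time_min))
  obs <- observation_set(lay$time_min, rowMeans(Y), 0.15 * rowMeans(Y),
                         lay$phase)
  r <- calibrate(table1_priors(), obs, n_models = 100, max_iter = 3,
                 dt = 1, seed = 45)
  expect_true(all(r$history$n_retained > 0))
  expect_true(r$converged)
})

test_that("fitted supports stay near the retained samples' range", {
  truth <- sample_gland(table1_priors(), seed = 7)
  st <- synthetic_study(truth = truth, noise_sd = 0.15, seed = 33)
  obs <- generate_observations(st)
  r <- calibrate(table1_priors(), obs, n_models = 150, max_iter = 1,
                 dt = 1, seed = 100)
  for (nm in c("k_d1", "k_d2", "beta", "m1")) {
    d <- r$spec[[nm]]
    s <- r$retained_draws[[nm]]
    pad <- 3.5 * d$bw
    expect_gte(d$lo, min(s) - pad)
    expect_lte(d$hi, max(s) + pad)
  }
})
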