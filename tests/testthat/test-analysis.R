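test_that("slope of an exact linear descent equals the line's own slope", {
  ca <- seq(1.0, 1.5, by = 0.005)
  pth <- 100 - (ca - 1.0) / 0.5 * 100  # 100% at 1.0 down to 0% at 1.5
  cur <- data.frame(ca = ca, pth = pth)
  # 90% crossing at 1.05, 10% at 1.45: 80 points over 0.4 mmol/L
  expect_equal(slope_10_90(cur), 200)
  expect_equal(slope_10_90(cur, normalize = "max"), 200)
})

test_that("slope matches the closed form for an analytic sigmoid", {
  # pth = D + (A-D)/(1+(ca/C)^B): crossing levels are analytic in ca
  A <- 10; D <- 1; C <- 1.2; B <- 24
  ca <- seq(0.6, 1.8, by = 0.001)
  cur <- data.frame(ca = ca, pth = D + (A - D) / (1 + (ca / C)^B))
  ca_at_level <- function(q) C * (1 / q - 1)^(1 / B)  # q = normalized height
  expected <- 80 / (ca_at_level(0.1) - ca_at_level(0.9))
  expect_equal(slope_10_90(cur), expected, tolerance = 1e-3)
})

test_that("slope is invariant under PTH rescaling and guards its range", {
  g <- sample_gland(table1_spec(), seed = 21)
  cur <- steady_curve(g)
  cur2 <- cur; cur2$pth <- cur2$pth * 1234
  expect_equal(slope_10_90(cur2), slope_10_90(cur))
  # under max-normalization the floor sits well above 10% of the maximum
  expect_error(slope_10_90(cur, normalize = "max"), "cross")
  expect_error(slope_10_90(data.frame(ca = cur$ca,
                                      pth = rep(1, nrow(cur)))), "flat")
})

test_that("four-parameter fit recovers exact generating parameters", {
  ca <- seq(0.8, 1.7, by = 0.01)
  truth <- c(A = 10, D = 1, C = 1.2, B = 8)
  y <- truth["D"] + (truth["A"] - truth["D"]) / (1 + (ca / truth["C"])^truth["B"])
  fit <- fit_four_param(data.frame(ca = ca, pth = unname(y)))
  expect_equal(unname(coef(fit)[c("A", "D", "C", "B")]),
               unname(truth), tolerance = 1e-4)
  expect_lt(fit$rss, 1e-10)
  # predict() reproduces the data
  expect_equal(predict(fit), unname(y), tolerance = 1e-6)
})

test_that("four-parameter fit is scale invariant in B and rejects flat data", {
  g <- sample_gland(table1_spec(), seed = 22)
  cur <- acute_response_curve(g)
  f1 <- fit_four_param(cur)
  cur2 <- cur; cur2$pth <- cur2$pth / max(cur2$pth)
  f2 <- fit_four_param(cur2)
  expect_equal(coef(f2)[["B"]], coef(f1)[["B"]], tolerance = 1e-3)
  flat <- data.frame(ca = seq(1, 1.5, by = 0.05), pth = rep(3, 11))
  expect_error(fit_four_param(flat), "flat")
})

test_that("ensemble bands honour quantile arithmetic and seeds", {
  spec <- table1_spec()
  pr <- clamp_protocol("A")
  b1 <- ensemble_band(spec, pr, n_runs = 4, dt = 2, seed = 30)
  b2 <- ensemble_band(spec, pr, n_runs = 4, dt = 2, seed = 30)
  expect_equal(as.data.frame(b1), as.data.frame(b2))
  expect_true(all(b1$lower <= b1$upper))
  # a (near-)degenerate population gives identical members: zero-width band
  eps <- 1e-9
  degen <- gland_spec(
    dist_uniform(3.6, 3.6 + eps), dist_uniform(2.1, 2.1 + eps),
    dist_uniform(0.5, 0.5 + eps), dist_uniform(0.0032, 0.0032 + eps),
    dist_uniform(270, 270 + eps), dist_uniform(244, 244 + eps),
    dist_uniform(1.13, 1.13 + eps), dist_uniform(1.27, 1.27 + eps),
    n_pairs = 2)
  b0 <- ensemble_band(degen, pr, n_runs = 3, dt = 2, seed = 31)
  expect_lt(max(b0$upper - b0$lower) / max(b0$upper), 1e-6)
})

test_that("coverage counts points inside the band", {
  band <- data.frame(t = 0:10, lower = rep(0, 11), upper = rep(1, 11))
  expect_equal(coverage(band, 0:10, rep(0.5, 11)), 100)
  expect_equal(coverage(band, 0:10, rep(2, 11)), 0)
  vals <- c(rep(0.5, 5), rep(5, 5))
  expect_equal(coverage(band, 1:10, vals), 50)
  expect_error(coverage(band, c(5, 12), c(1, 1)), "range")
})

test_that("direction score applies the dead band and counts agreement", {
  t <- c(0, 10, 20, 30)
  obs <- data.frame(time = t, value = c(5, 8, 8.2, 4))
  same <- data.frame(time = t, value = c(5, 8, 8.2, 4))
  expect_equal(direction_score(same, obs)$n_agree, 3)
  neg <- data.frame(time = t, value = c(8, 5, 4.8, 9))
  expect_equal(direction_score(neg, obs)$n_agree, 1)  # dead-band interval agrees
  # hand-built: model signs (+,0,-) vs obs (+,0,-) with dead band 0.5
  model <- data.frame(time = t, value = c(1, 3, 3.3, 1))
  ds <- direction_score(model, obs)
  expect_equal(ds$model_sign, c(1, 0, -1))
  expect_equal(ds$obs_sign, c(1, 0, -1))
  expect_equal(ds$n_agree, 3); expect_equal(ds$n_total, 3)
  expect_error(direction_score(model, obs[1:3, ]), "grid")
})

test_that("memoryless prediction shows exactly zero hysteresis", {
  ca <- seq(0.8, 1.7, by = 0.01)
  y <- 1 + 9 / (1 + (ca / 1.2)^8)
  fit <- fit_four_param(data.frame(ca = ca, pth = y))
  pr <- clamp_protocol("A")
  tt <- seq(0, 200, by = 0.5)
  bp <- brown_prediction(fit, pr, tt)
  # constant profile -> constant output
  flat <- brown_prediction(fit, constant_profile(1.25, 100), seq(0, 100, 1))
  expect_equal(diff(range(flat$pth)), 0)
  # the two hypocalcemic plateaus predict identical PTH
  expect_equal(bp$pth[bp$t == 45], bp$pth[bp$t == 160])
  # symmetric round-trip excursion encloses zero area
  tri <- profile_from_table(c(0, 40, 80), c(1.25, 1.05, 1.25))
  rt <- brown_prediction(fit, tri, seq(0, 80, by = 0.5))
  expect_equal(hysteresis_loop_area(rt$ca, rt$pth), 0, tolerance = 1e-9)
})

test_that("squared residuals accumulate as expected", {
  g <- pair_gland()
  sim <- simulate_gland(g, clamp_protocol("A"), dt = 0.5, t_end = 100)
  t <- c(0, 20, 50, 80)
  y <- serum_at(sim, t)
  expect_equal(squared_residuals(sim, t, y), 0)
  expect_equal(squared_residuals(sim, t, y + 1), 4)
  expect_equal(squared_residuals(sim, t, y + c(1, -2, 0, 3)), 1 + 4 + 0 + 9)
})

test_that("peak prominence is zero for monotone windows", {
  g <- pair_gland()
  sim <- simulate_gland(g, constant_profile(1.25, 50), dt = 0.5)
  expect_equal(peak_prominence(sim, c(10, 40)), 0)
})
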