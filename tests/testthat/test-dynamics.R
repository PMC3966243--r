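test_that("derivatives reduce to synthesis-only when fluxes vanish", {
  g <- pair_gland()
  st <- system_state(0, 0, 0, c(0, 0))
  d <- pth_derivatives(st, 1.25, g)
  expect_equal(d$dvpth, g$params$k_v)
  expect_equal(d$dserum_pth, 0)
  expect_equal(d$disf_pth, 0)
})

test_that("compartment exchange conserves mass", {
  g <- pair_gland()
  const <- physio_constants(renal_extraction = 1e-9,
                            hepatic_extraction = 1e-9)
  st <- system_state(0, 10, 2, c(0, 0))
  d <- pth_derivatives(st, 1.25, g, const)
  # serum mass loss rate equals isf mass gain rate (S ~ 0, k_cl ~ 0)
  expect_equal(-d$dserum_pth * const$serum_volume,
               d$disf_pth * const$isf_volume, tolerance = 1e-6)
})

test_that("derivatives vanish at the closed-form steady state", {
  set.seed(7)
  for (i in 1:5) {
    g <- random_gland()
    ss <- steady_state(1.1, g)
    d <- pth_derivatives(ss, 1.1, g)
    expect_lt(max(abs(c(d$dvpth, d$dserum_pth, d$disf_pth))), 1e-10)
  }
})

test_that("steady state matches long-run integration", {
  set.seed(8)
  const <- physio_constants()
  for (i in 1:5) {
    g <- random_gland()
    ss <- steady_state(1.2, g, const)
    init <- system_state(0, 5, 1, rep(10, n_populations(g)))
    sim <- simulate_gland(g, constant_profile(1.2, 800), const,
                          dt = 1, init = init)
    expect_equal(sim$serum_pth[nrow(sim)], ss$serum_pth, tolerance = 1e-3)
    expect_equal(sim$isf_pth[nrow(sim)], ss$isf_pth, tolerance = 1e-3)
  }
})

test_that("steady state is zero without synthesis and errors without clearance", {
  g <- pair_gland()
  g$params$k_v <- c(0, 0)
  ss <- steady_state(1.25, g)
  expect_equal(ss$serum_pth, 0)
  expect_equal(ss$vpth, c(0, 0))
  expect_error(
    steady_state(1.25, pair_gland(),
                 physio_constants(renal_extraction = 1e-300,
                                  hepatic_extraction = 1e-300)),
    NA)  # tiny but positive clearance is finite (huge serum), not an error
  expect_error(pth_derivatives(system_state(0, 1, 1, c(1, 1, 1)), 1.2,
                               pair_gland()),
               "populations")
})

test_that("steady-state serum PTH is non-increasing in calcium", {
  set.seed(9)
  for (i in 1:5) {
    g <- random_gland()
    cur <- steady_curve(g, ca_grid = seq(0.6, 1.8, by = 0.01))
    expect_true(all(diff(cur$pth) <= 1e-12))
  }
})

test_that("constant clamp at steady init stays flat", {
  g <- pair_gland()
  sim <- simulate_gland(g, constant_profile(1.25, 300), dt = 0.5)
  dev <- max(abs(sim$serum_pth - sim$serum_pth[1])) / sim$serum_pth[1]
  expect_lt(dev, 1e-3)
})

test_that("halving the step changes the solution by less than 0.5%", {
  g <- pair_gland()
  pr <- clamp_protocol("A")
  s1 <- simulate_gland(g, pr, dt = 0.2)
  s2 <- simulate_gland(g, pr, dt = 0.1)
  y2 <- serum_at(s2, s1$t)
  expect_lt(max(abs(s1$serum_pth - y2) / pmax(y2, 1e-9)), 0.005)
})

test_that("mass bookkeeping closes over a full protocol", {
  g <- pair_gland()
  sim <- simulate_gland(g, clamp_protocol("A"), dt = 0.1)
  mb <- mass_balance(sim)
  expect_lt(abs(mb$residual) / mb$secreted, 1e-4)
})

test_that("homogeneous populations preserve steady state and bookkeeping", {
  g <- uniform_gland()
  ss <- steady_state(1.2, g)
  # every population identical => identical stores
  expect_equal(diff(range(ss$vpth)), 0)
  sim <- simulate_gland(g, clamp_protocol("A"), dt = 0.2)
  mb <- mass_balance(sim)
  expect_lt(abs(mb$residual) / mb$secreted, 1e-3)
})

test_that("simulation guards its inputs", {
  g <- pair_gland()
  pr <- clamp_protocol("A")
  expect_error(simulate_gland(g, pr, dt = 0), "dt")
  expect_error(simulate_gland(g, pr, t_end = 1000), "undefined")
  expect_error(simulate_gland(g, pr, init = system_state(0, 1, 1, rep(1, 5))),
               "match")
})
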