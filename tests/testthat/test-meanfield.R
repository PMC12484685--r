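test_that("transfer function matches the logistic sigmoid", {
  expect_equal(transfer(0), 0.5)
  x <- c(0.3, 1.7, -2.2, 5)
  expect_equal(transfer(x) + transfer(-x), rep(1, length(x)))
  expect_equal(transfer(-2.4), 0.083173, tolerance = 1e-5)
  # monotone and saturating without overflow
  expect_true(all(diff(transfer(seq(-800, 800, by = 10))) >= 0))
  expect_equal(transfer(800), 1)
})

test_that("depression recruitment is sigmoidal with half-maximum at theta", {
  pp <- stp_params(theta = 0.2)
  expect_equal(recruitment(0.2, pp), 1)  # m/2 with m = 2
  expect_equal(recruitment(1, pp), 2 / (1 + exp(-40)), tolerance = 1e-12)
  expect_equal(recruitment(0, pp), 2 / (1 + exp(10)), tolerance = 1e-12)
  expect_equal(recruitment(0, pp), 9.08e-5, tolerance = 1e-2)
})

test_that("efficacy fixed point gives the depressed-state value 0.11", {
  pp <- stp_params(theta = 0.2)
  expect_equal(round(plasticity_fixed_point(1, pp), 2), 0.11)
  expect_equal(plasticity_fixed_point(1, pp), 1 / 9, tolerance = 1e-4)
  expect_equal(plasticity_fixed_point(0, pp), 0.999637, tolerance = 1e-5)
  # no recruitment: efficacy stays at 1 for any activity
  pp0 <- stp_params(m = 0, theta = 0.2)
  expect_equal(plasticity_fixed_point(c(0, 0.5, 1), pp0), rep(1, 3))
  # monotone non-increasing in r_e, always in (0, 1]
  ph <- plasticity_fixed_point(seq(0, 1, by = 0.01), pp)
  expect_true(all(diff(ph) <= 0))
  expect_true(all(ph > 0 & ph <= 1))
})

test_that("efficacy step is the exact exponential update", {
  pp <- stp_params(theta = 0.2)
  expect_equal(plasticity_step(0.7, 0.5, 0, pp), 0.7)
  expect_equal(plasticity_step(0.9, 1, 1e6, pp),
               plasticity_fixed_point(1, pp), tolerance = 1e-12)
  expect_error(plasticity_step(0.5, 0.5, -1, pp), "non-negative")
  # composition over split intervals equals a single step exactly
  p1 <- plasticity_step(1, 0.6, 2.5, pp)
  p2 <- 1
  for (i in 1:10) p2 <- plasticity_step(p2, 0.6, 0.25, pp)
  expect_equal(p1, p2, tolerance = 1e-12)
  # against an independent fine-step RK4 integration
  expect_equal(plasticity_step(1, 1, 1, pp),
               rk4_plasticity(1, 1, 1, pp), tolerance = 1e-10)
})

test_that("decoupled network equilibrates at transfer of the bare drive", {
  mp <- mf_params(j_ee = 0, j_ei = 0, j_ie = 0, j_ii = 0, i_e = 0, i_i = 0)
  s <- network_state(0.5, 0.5, 1, 1)
  d <- meanfield_rhs(s, mp, pp_ee_at(0.5), pp_ie_at(0.2))
  expect_equal(d[["r_e"]], 0)
  expect_equal(d[["r_i"]], 0)
  # nonzero drives: equilibrium activations equal transfer(sqrt(N) * I)
  mp2 <- mf_params(j_ee = 0, j_ei = 0, j_ie = 0, j_ii = 0)
  star <- network_state(transfer(sqrt(mp2$N) * mp2$i_e),
                        transfer(sqrt(mp2$N) * mp2$i_i),
                        plasticity_fixed_point(transfer(sqrt(mp2$N) * mp2$i_e),
                                               pp_ee_at(0.5)),
                        plasticity_fixed_point(transfer(sqrt(mp2$N) * mp2$i_e),
                                               pp_ie_at(0.2)))
  d2 <- meanfield_rhs(star, mp2, pp_ee_at(0.5), pp_ie_at(0.2))
  expect_true(all(abs(d2) < 1e-9))
})

test_that("reduced modes freeze the corresponding efficacy", {
  mp <- mf_params()
  s <- network_state(0.3, 0.2, 0.6, 0.4)
  expect_equal(meanfield_rhs(s, mp, pp_ee_at(0.5), pp_ie_at(0.2),
                             mode = "fixed_pee")[["p_ee"]], 0)
  expect_equal(meanfield_rhs(s, mp, pp_ee_at(0.5), pp_ie_at(0.2),
                             mode = "fixed_pie")[["p_ie"]], 0)
})

test_that("integration holds a stable fixed point and respects tolerances", {
  mp <- mf_params(j_ee = 0, j_ei = 0, j_ie = 0, j_ii = 0)
  re_star <- transfer(sqrt(mp$N) * mp$i_e)
  init <- network_state(re_star, transfer(sqrt(mp$N) * mp$i_i),
                        plasticity_fixed_point(re_star, pp_ee_at(0.5)),
                        plasticity_fixed_point(re_star, pp_ie_at(0.2)))
  sim <- simulate_meanfield(init, mp, pp_ee_at(0.5), pp_ie_at(0.2), T = 50)
  expect_true(max(abs(sim$r_e - re_star)) < 1e-6)

  # halving tolerances barely changes the endpoint
  mp2 <- mf_params()
  init2 <- network_state(0.8, 0.5, 0.5, 0.11)
  a <- simulate_meanfield(init2, mp2, pp_ee_at(0.5), pp_ie_at(0.2),
                          mode = "fixed_pie", T = 60,
                          rtol = 1e-8, atol = 1e-10)
  b <- simulate_meanfield(init2, mp2, pp_ee_at(0.5), pp_ie_at(0.2),
                          mode = "fixed_pie", T = 60,
                          rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(tail(a$r_e, 1) - tail(b$r_e, 1))), 1e-6)
})

test_that("trajectories stay inside the unit box across parameter draws", {
  set.seed(11)
  for (k in 1:8) {
    mp <- mf_params(K = sample(c(200, 400, 1000), 1))
    ppe <- stp_params(theta = runif(1))
    ppi <- stp_params(theta = runif(1))
    init <- network_state(runif(1), runif(1), runif(1, 0.1, 1),
                          runif(1, 0.1, 1))
    sim <- simulate_meanfield(init, mp, ppe, ppi, T = 80, dt_out = 0.1)
    vals <- unlist(sim[, c("r_e", "r_i", "p_ee", "p_ie")])
    expect_true(all(vals > -1e-6 & vals < 1 + 1e-6))
  }
})

test_that("depressed E-to-I pathway sustains a within-event oscillation", {
  mp <- mf_params()  # K = 400, effective size 1000
  init <- network_state(0.8, 0.5, 0.5, 0.11)
  sim <- simulate_meanfield(init, mp, pp_ee_at(0.5), pp_ie_at(0.2),
                            mode = "fixed_pie", T = 200)
  late <- sim$r_e[sim$t > 100]
  expect_gt(diff(range(late)), 0.5)  # large sustained excursions
})

test_that("a strong pulse switches the bistable reduced model to the high branch", {
  mp <- mf_params()
  # event-initiation reduced model (p_ee = 1), bistable threshold regime
  init <- network_state(0.05, 0.08, 1,
                        plasticity_fixed_point(0.05, pp_ie_at(0.4)))
  quiet <- simulate_meanfield(init, pp_ee = pp_ee_at(0.5),
                              pp_ie = pp_ie_at(0.4), mp = mp,
                              mode = "fixed_pee", T = 800)
  expect_lt(tail(quiet$r_e, 1), 0.3)  # stays on the low branch unperturbed
  stim <- simulate_meanfield(init, pp_ee = pp_ee_at(0.5),
                             pp_ie = pp_ie_at(0.4), mp = mp,
                             mode = "fixed_pee", T = 800,
                             stim = list(amplitude = 0.3, on = 300, off = 500))
  expect_gt(tail(stim$r_e, 1), 0.7)   # switched to the high branch and stays
})
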