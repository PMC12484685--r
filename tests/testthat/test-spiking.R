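test_that("network realisations respect connection probabilities", {
  np <- neuron_params()
  sp0 <- synapse_params(chi = matrix(0, 2, 2,
                                     dimnames = list(c("E", "I"),
                                                     c("E", "I"))))
  net0 <- build_network(50, 20, sp0, np, seed = 1)
  expect_equal(length(net0$adjE_idx), 0L)
  expect_equal(length(net0$adjI_idx), 0L)

  sp1 <- synapse_params(chi = matrix(1, 2, 2,
                                     dimnames = list(c("E", "I"),
                                                     c("E", "I"))))
  net1 <- build_network(30, 10, sp1, np, seed = 1)
  expect_equal(length(net1$adjE_idx), 40 * 30)  # complete blocks
  expect_equal(length(net1$adjI_idx), 40 * 10)

  net <- build_network(1000, 1000, synapse_params(), np, seed = 2)
  dens <- length(net$adjE_idx) / (2000 * 1000)
  se <- sqrt(0.2 * 0.8 / (2000 * 1000))
  expect_lt(abs(dens - 0.2), 3 * se)
  # reproducible by seed
  net_b <- build_network(1000, 1000, synapse_params(), np, seed = 2)
  expect_identical(net$adjE_idx, net_b$adjE_idx)
  expect_identical(net$mu, net_b$mu)
})

test_that("plasticity updates follow the multiplicative/additive rule", {
  f0 <- list(D = 1, F = 1)
  f1 <- stp_on_spike(f0, d = 0.24, f = 0.85)
  expect_equal(f1$D, 0.24)
  expect_equal(f1$F, 1.85)
  # no facilitation: F stays 1 after any spike
  expect_equal(stp_on_spike(f0, d = 0.24, f = 0)$F, 1)
  # static synapse
  fs <- stp_on_spike(f0, d = 1, f = 0)
  expect_equal(fs, f0)
})

test_that("factor recovery is exactly exponential towards one", {
  f0 <- list(D = 0.2, F = 2.5)
  expect_equal(stp_decay(f0, 0, 200, 300), f0)
  far <- stp_decay(f0, 1e5, 200, 300)
  expect_equal(far$D, 1, tolerance = 1e-6)
  expect_equal(far$F, 1, tolerance = 1e-6)
  # semigroup property over split intervals
  one <- stp_decay(f0, 50, 200, 300)
  two <- stp_decay(stp_decay(f0, 20, 200, 300), 30, 200, 300)
  expect_equal(one$D, two$D, tolerance = 1e-12)
  expect_equal(one$F, two$F, tolerance = 1e-12)
})

test_that("synaptic kernel is a normalised difference of exponentials", {
  expect_equal(synaptic_kernel(0, 1, 5), 0)
  tt <- seq(0, 100, by = 0.001)
  integral <- sum(synaptic_kernel(tt, 1, 5)) * 0.001
  expect_equal(integral, 1, tolerance = 1e-6)
  # analytic argmax
  tstar <- 5 * 1 / (5 - 1) * log(5 / 1)
  grid <- seq(0, 20, by = 1e-4)
  expect_equal(grid[which.max(synaptic_kernel(grid, 1, 5))], tstar,
               tolerance = 1e-3)
  # alpha-function limit for equal timescales
  a <- synaptic_kernel(tt, 2, 2)
  expect_equal(sum(a) * 0.001, 1, tolerance = 1e-6)
  expect_equal(grid[which.max(synaptic_kernel(grid, 2, 2))], 2,
               tolerance = 1e-3)
})

test_that("five-pulse ratio reproduces the pathway asymmetry", {
  sp <- synapse_params()
  # static synapse: ratio exactly 1
  sp_static <- synapse_params(d_ee = 1, f_ee = 0)
  expect_equal(five_pulse_ratio(sp_static, 20, "EE"), 1, tolerance = 1e-6)
  # facilitation balances depression at low rates for the E-to-E pathway
  expect_equal(five_pulse_ratio(sp, 15, "EE"), 1, tolerance = 0.15)
  # purely depressing E-to-I pathway is weaker at every tested rate
  for (r in c(10, 20, 40, 60))
    expect_gt(five_pulse_ratio(sp, r, "EE"), five_pulse_ratio(sp, r, "IE"))
  # depression dominates at high rates even with facilitation
  expect_lt(five_pulse_ratio(sp, 60, "EE"), 0.7)
})

test_that("silent network stays silent and the refractory period holds", {
  np <- neuron_params(mu_e = c(0.3, 0.5), mu_i = c(0.3, 0.5),
                      sigma_e = 0, sigma_i = 0)
  sp <- synapse_params(chi = matrix(0, 2, 2,
                                    dimnames = list(c("E", "I"),
                                                    c("E", "I"))))
  net <- build_network(40, 10, sp, np, seed = 3)
  sim <- simulate_spiking(net, T_ms = 500, seed = 4)
  expect_equal(nrow(sim$spikes), 0L)

  # drive some neurons hard: inter-spike intervals respect tau_ref
  np2 <- neuron_params(mu_e = c(1.4, 1.6), mu_i = c(0.3, 0.5),
                       sigma_e = 0.05, sigma_i = 0)
  net2 <- build_network(20, 5, sp, np2, seed = 5)
  sim2 <- simulate_spiking(net2, T_ms = 500, seed = 6)
  expect_gt(nrow(sim2$spikes), 50)
  for (id in unique(sim2$spikes$id)) {
    isi <- diff(sim2$spikes$t_ms[sim2$spikes$id == id])
    expect_true(all(isi >= net2$np$tau_ref))
  }
  # determinism
  sim2b <- simulate_spiking(net2, T_ms = 500, seed = 6)
  expect_identical(sim2$spikes, sim2b$spikes)
})

test_that("population rate is a faithful count normalisation", {
  empty <- list(spikes = data.frame(id = integer(0), t_ms = numeric(0)),
                N_E = 10, N_I = 5, T_ms = 100)
  class(empty) <- "lif_sim"
  r0 <- population_rate(empty)
  expect_true(all(r0$rate_hz == 0))

  # Poisson surrogate at 5 Hz
  set.seed(7)
  N <- 200; T_ms <- 5000; lam <- 5
  n_sp <- rpois(1, N * lam * T_ms / 1000)
  spikes <- data.frame(id = sample.int(N, n_sp, replace = TRUE),
                       t_ms = runif(n_sp, 0, T_ms))
  sur <- list(spikes = spikes, N_E = N, N_I = 0, T_ms = T_ms)
  class(sur) <- "lif_sim"
  r <- population_rate(sur, bin_ms = 50)
  se <- sqrt(lam / (N * 0.05)) / sqrt(nrow(r))
  expect_lt(abs(mean(r$rate_hz) - lam), 3 * se)
  # conservation: total rate integrates back to the spike count
  expect_equal(sum(r$rate_hz * 0.05) * N, n_sp, tolerance = 1e-10)
})

test_that("current correlations recognise identical and independent inputs", {
  set.seed(8)
  n_t <- 2000
  shared <- rnorm(n_t)
  ident <- list(i_exc = cbind(shared, shared),
                i_inh = cbind(-0.5 * shared, -0.5 * shared))
  cc <- current_correlations(ident)
  non <- cc[cc$period == "nonevent", ]
  expect_equal(non$correlation[non$type == "EE"], 1)
  expect_equal(non$correlation[non$type == "II"], 1)

  indep <- list(i_exc = matrix(rnorm(3 * n_t), ncol = 3),
                i_inh = matrix(rnorm(3 * n_t), ncol = 3))
  ci <- current_correlations(indep)
  expect_true(all(abs(ci$correlation[ci$period == "nonevent"]) < 0.1))
  # constant traces are excluded with a warning
  const <- list(i_exc = cbind(rep(1, 50), rep(1, 50)),
                i_inh = cbind(rnorm(50), rnorm(50)))
  expect_warning(current_correlations(const), "constant")
})

test_that("kick protocol draws reproducible amplitudes in the stated window", {
  k <- kick_protocol(1:200, t_on = 1000, tau_e = 20, seed = 11)
  expect_equal(k$off - k$on, 80)
  expect_equal(length(k$amp), 200)
  expect_equal(mean(k$amp), 17.1 / 20, tolerance = 0.05)
  expect_equal(sd(k$amp), sqrt(5e-2), tolerance = 0.1)
  k2 <- kick_protocol(1:200, t_on = 1000, tau_e = 20, seed = 11)
  expect_identical(k$amp, k2$amp)
})

test_that("kick selection returns the highest-rate excitatory neurons", {
  spikes <- data.frame(id = c(rep(1L, 10), rep(2L, 5), rep(3L, 1), 6L),
                       t_ms = 1:17)
  base <- list(spikes = spikes, N_E = 5, N_I = 2, T_ms = 100)
  class(base) <- "lif_sim"
  expect_equal(select_kick_targets(base, n = 2), c(1L, 2L))
  expect_true(all(select_kick_targets(base, n = 4) <= 5))
})

test_that("shared inhibition partially cancels shared excitation at baseline", {
  prof <- spiking_profile(f_ie = 0)
  net <- build_network(prof$N_E, prof$N_I, prof$sp, prof$np, seed = 3)
  sim <- simulate_spiking(net, T_ms = 4000, seed = 4, record_idx = 101:124,
                          record_stride = 10L)
  keep <- sim$currents$t > 500  # discard onset transient
  cc <- current_correlations(list(i_exc = sim$currents$i_exc[keep, ],
                                  i_inh = sim$currents$i_inh[keep, ]))
  non <- cc[cc$period == "nonevent", ]
  comp <- non$correlation[non$type == "composite"]
  expect_lt(comp, non$correlation[non$type == "EE"])
  expect_lt(comp, non$correlation[non$type == "II"])
})

test_that("halving the time step leaves the baseline rate within 10%", {
  prof <- spiking_profile(f_ie = 0)
  net <- build_network(prof$N_E, prof$N_I, prof$sp, prof$np, seed = 5)
  rate_at <- function(dt) {
    sim <- simulate_spiking(net, T_ms = 2500, seed = 11, dt = dt)
    sp <- sim$spikes[sim$spikes$t_ms > 500, ]
    sum(sp$id <= net$N_E) / net$N_E / 2
  }
  r_coarse <- rate_at(0.1)
  r_fine <- rate_at(0.05)
  expect_lt(abs(r_fine - r_coarse) / r_coarse, 0.10)
})
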