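# shared fixtures: canonical parameter sets used across tests
default_mp <- function(...) mf_params(...)

pp_ee_at <- function(theta) stp_params(theta = theta)
pp_ie_at <- function(theta) stp_params(theta = theta)

# fine-step RK4 integration of the efficacy ODE at frozen r_e; independent
# oracle for the exact exponential update
rk4_plasticity <- function(p0, r_e, T, pp, dt = 1e-4) {
  f <- function(p) (1 - p) / pp$tau_r - recruitment(r_e, pp) * p / pp$tau_d
  p <- p0
  for (i in seq_len(round(T / dt))) {
    k1 <- f(p)
    k2 <- f(p + dt / 2 * k1)
    k3 <- f(p + dt / 2 * k2)
    k4 <- f(p + dt * k3)
    p <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  p
}

# stationary distribution of the two-population birth-death master equation
# for tiny populations with frozen efficacies, solved directly
tiny_master_stationary <- function(N, mp, p_ee = 1, p_ie = 1) {
  states <- expand.grid(n = 0:N, m = 0:N)
  ns <- nrow(states)
  idx <- function(n, m) n + 1L + (N + 1L) * m
  Q <- matrix(0, ns, ns)
  for (k in seq_len(ns)) {
    n <- states$n[k]; m <- states$m[k]
    rates <- transition_rates(n, m, p_ee, p_ie, mp, N_E = N, N_I = N)
    if (n < N) Q[k, idx(n + 1L, m)] <- rates[["e_birth"]]
    if (n > 0) Q[k, idx(n - 1L, m)] <- rates[["e_death"]]
    if (m < N) Q[k, idx(n, m + 1L)] <- rates[["i_birth"]]
    if (m > 0) Q[k, idx(n, m - 1L)] <- rates[["i_death"]]
  }
  diag(Q) <- -rowSums(Q)
  # solve pi Q = 0 with sum(pi) = 1
  A <- rbind(t(Q), rep(1, ns))
  b <- c(rep(0, ns), 1)
  pi_hat <- qr.solve(A, b)
  pi_hat[pi_hat < 0] <- 0
  data.frame(n = states$n, m = states$m, p = pi_hat / sum(pi_hat))
}
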