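#' Sigmoidal population transfer function
#'
#' The logistic transfer \eqn{f(x) = 1/(1 + e^{-x})} mapping net input to the
#' activation probability of a population.  Saturates gracefully for large
#' `|x|` (no overflow).
#'
#' @param x Numeric vector of net inputs.
#' @return Values in (0, 1), strictly increasing in `x`.
#' @examples
#' transfer(0)        # 0.5
#' transfer(-2.4)     # ~ 0.0832
#' @export
transfer <- function(x) {
  # plogis-style stable evaluation
  ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
}

#' Depression recruitment rate
#'
#' Sigmoidal recruitment \eqn{a(r) = m/(1 + e^{-\beta (r - \theta)})} of
#' synaptic depression as a function of presynaptic excitatory activation.
#'
#' @param r_e Excitatory activation(s) in \[0, 1\].
#' @param pp [stp_params()].
#' @return Recruitment rate(s) in \[0, m\], equal to `m/2` at `r_e = theta`.
#' @export
recruitment <- function(r_e, pp) {
  pp$m * transfer(pp$beta * (r_e - pp$theta))
}

#' Equilibrium synaptic efficacy at frozen activity
#'
#' Closed-form fixed point \eqn{\hat p = (1/\tau_r) / (1/\tau_r +
#' a(r_E)/\tau_d)} of the efficacy dynamics at constant `r_e`; globally
#' attracting.  Near-unity for quiescent activity and ~0.11 at saturated
#' activity under the default parameters with `theta = 0.2`.
#'
#' @inheritParams recruitment
#' @return Efficacy in (0, 1\], non-increasing in `r_e`.
#' @export
plasticity_fixed_point <- function(r_e, pp) {
  kr <- 1 / pp$tau_r
  kr / (kr + recruitment(r_e, pp) / pp$tau_d)
}

#' Exact efficacy update over a time step
#'
#' With `r_e` frozen, the efficacy ODE is linear and the update over `dt` is
#' the exact exponential relaxation
#' \eqn{p(t+dt) = \hat p + (p - \hat p) e^{-\lambda dt}} with
#' \eqn{\lambda = 1/\tau_r + a(r_E)/\tau_d}.  Composing steps over split
#' intervals is exactly equivalent to a single step.
#'
#' @param p Current efficacy in (0, 1\].
#' @param r_e Frozen excitatory activation.
#' @param dt Time step (>= 0, model units).
#' @param pp [stp_params()].
#' @return Updated efficacy, still in (0, 1\].
#' @export
plasticity_step <- function(p, r_e, dt, pp) {
  if (any(dt < 0)) stop("dt must be non-negative", call. = FALSE)
  lambda <- 1 / pp$tau_r + recruitment(r_e, pp) / pp$tau_d
  p_hat <- (1 / pp$tau_r) / lambda
  p_hat + (p - p_hat) * exp(-lambda * dt)
}

mode_choices <- c("full", "fixed_pee", "fixed_pie")

#' Right-hand side of the mean-field rate model
#'
#' Time derivatives of the state `(r_e, r_i, p_ee, p_ie)`:
#' \deqn{\dot r_E = -r_E + f(\sqrt{N}(j_{EE} p_{EE} r_E - j_{EI} r_I + I_E))}
#' \deqn{\tau_I \dot r_I = -r_I + f(\sqrt{N}(j_{IE} p_{IE} r_E - j_{II} r_I + I_I))}
#' with the efficacy dynamics of [stp_params()] for each depressing pathway.
#' In the reduced modes one efficacy is frozen (zero derivative): `fixed_pee`
#' freezes `p_ee` (undepressed E-to-E, event-initiation analysis) and
#' `fixed_pie` freezes `p_ie` (depressed E-to-I, within-event analysis).
#'
#' @param state Named state vector as from [network_state()].
#' @param mp [mf_params()].
#' @param pp_ee,pp_ie [stp_params()] for the E-to-E and E-to-I pathways.
#' @param mode One of `"full"`, `"fixed_pee"`, `"fixed_pie"`.
#' @return Named derivative vector `(r_e, r_i, p_ee, p_ie)`.
#' @export
meanfield_rhs <- function(state, mp, pp_ee, pp_ie, mode = "full") {
  mode <- match.arg(mode, mode_choices)
  sN <- sqrt(mp$N)
  r_e <- state[["r_e"]]; r_i <- state[["r_i"]]
  p_ee <- state[["p_ee"]]; p_ie <- state[["p_ie"]]
  d_re <- -r_e + transfer(sN * (mp$j_ee * p_ee * r_e - mp$j_ei * r_i + mp$i_e))
  d_ri <- (-r_i + transfer(sN * (mp$j_ie * p_ie * r_e - mp$j_ii * r_i + mp$i_i))) / mp$tau_i
  d_pee <- (1 - p_ee) / pp_ee$tau_r - recruitment(r_e, pp_ee) * p_ee / pp_ee$tau_d
  d_pie <- (1 - p_ie) / pp_ie$tau_r - recruitment(r_e, pp_ie) * p_ie / pp_ie$tau_d
  if (mode == "fixed_pee") d_pee <- 0
  if (mode == "fixed_pie") d_pie <- 0
  c(r_e = d_re, r_i = d_ri, p_ee = d_pee, p_ie = d_pie)
}

#' Integrate the deterministic rate model
#'
#' Adaptive-step integration (LSODA) of the mean-field system, sampled on a
#' uniform output grid.  An optional stimulation protocol adds a square pulse
#' to the excitatory drive, mimicking transient external input.
#'
#' @param init Initial state ([network_state()]); frozen components are taken
#'   from `init` in the reduced modes.
#' @param mp,pp_ee,pp_ie,mode See [meanfield_rhs()].
#' @param T Total integration time (model units, > 0).
#' @param dt_out Output sampling interval.
#' @param stim Optional list `list(amplitude=, on=, off=)`: additive pulse to
#'   `i_e` for `on <= t < off`.
#' @param rtol,atol Integrator tolerances.
#' @return A data frame of class `"mf_sim"` with columns
#'   `t, r_e, r_i, p_ee, p_ie` and attributes `mode` and `time_unit_ms`.
#' @examples
#' mp <- mf_params(); pp <- stp_params(theta = 0.5)
#' sim <- simulate_meanfield(network_state(0.8, 0.5, 0.5, 0.11),
#'                           mp, pp, stp_params(theta = 0.2),
#'                           mode = "fixed_pie", T = 100)
#' @export
simulate_meanfield <- function(init, mp, pp_ee, pp_ie, mode = "full",
                               T = 100, dt_out = 0.05, stim = NULL,
                               rtol = 1e-8, atol = 1e-10) {
  mode <- match.arg(mode, mode_choices)
  stopifnot(T > 0, dt_out > 0)
  stim_amp <- if (is.null(stim)) 0 else stim$amplitude
  deriv <- function(t, y, parms) {
    mp_t <- mp
    if (stim_amp != 0 && t >= stim$on && t < stim$off)
      mp_t$i_e <- mp_t$i_e + stim_amp
    list(meanfield_rhs(y, mp_t, pp_ee, pp_ie, mode))
  }
  times <- seq(0, T, by = dt_out)
  out <- deSolve::ode(init, times, deriv, NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0)
    stop(sprintf("integrator failed near t = %.4g", max(out[, 1])),
         call. = FALSE)
  df <- as.data.frame(out)
  names(df)[1] <- "t"
  structure(df, class = c("mf_sim", "data.frame"),
            mode = mode, time_unit_ms = mp$time_unit_ms)
}

#' @export
print.mf_sim <- function(x, ...) {
  cat(sprintf("Mean-field trajectory (%s mode): %d samples over %g time units\n",
              attr(x, "mode"), nrow(x), max(x$t)))
  cat(sprintf("  final state: r_e=%.4f r_i=%.4f p_ee=%.4f p_ie=%.4f\n",
              tail(x$r_e, 1), tail(x$r_i, 1), tail(x$p_ee, 1), tail(x$p_ie, 1)))
  invisible(x)
}

#' @export
plot.mf_sim <- function(x, ...) {
  tu <- attr(x, "time_unit_ms")
  graphics::matplot(x$t * tu / 1000, cbind(x$r_e, x$r_i, x$p_ee, x$p_ie),
                    type = "l", lty = 1,
                    col = c("firebrick", "steelblue", "darkorange", "purple"),
                    xlab = "time (s)", ylab = "activation / efficacy", ...)
  graphics::legend("topright", c("r_E", "r_I", "p_EE", "p_IE"), lty = 1,
                   col = c("firebrick", "steelblue", "darkorange", "purple"),
                   bty = "n")
  invisible(x)
}
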