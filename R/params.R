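#' Mean-field network parameters
#'
#' Couplings, drives and size constants of the two-population balanced-network
#' rate model.  Synaptic strengths scale as \eqn{j/\sqrt{N}} so that recurrent
#' excitation and inhibition individually grow with network size but cancel to
#' order one (the balance condition); the effective size \eqn{N = K/c} (mean
#' in-degree \eqn{K} over connection density \eqn{c}) therefore enters the
#' transfer-function argument as \eqn{\sqrt{N}}.
#'
#' All couplings are positive by convention; the inhibitory terms carry an
#' explicit minus sign in the rate equations.  Time is measured in units of
#' the excitatory relaxation time, converted to milliseconds through
#' `time_unit_ms` (default 10 ms per unit).
#'
#' @param j_ee,j_ei,j_ie,j_ii Non-negative dimensionless coupling strengths
#'   (postsynaptic population first: `j_ie` is E onto I).
#' @param i_e,i_i External drives (order one, may be negative).
#' @param tau_i Inhibitory time constant relative to excitatory (> 0).
#' @param K Mean number of connections per neuron (>= 1).
#' @param c Connection density `K/N` in (0, 1]; the effective size used in
#'   the transfer gain is `N = K/c`.
#' @param time_unit_ms Real time per model time unit, in milliseconds.
#'
#' @return An object of class `"mf_params"`.
#' @examples
#' mp <- mf_params()
#' mp$N  # effective size entering sqrt(N)
#' @export
mf_params <- function(j_ee = 2, j_ei = 1, j_ie = 5, j_ii = 2,
                      i_e = -0.12, i_i = -0.2, tau_i = 1,
                      K = 400, c = 0.4, time_unit_ms = 10) {
  stopifnot(j_ee >= 0, j_ei >= 0, j_ie >= 0, j_ii >= 0,
            tau_i > 0, K >= 1, c > 0, c <= 1, time_unit_ms > 0)
  structure(list(j_ee = j_ee, j_ei = j_ei, j_ie = j_ie, j_ii = j_ii,
                 i_e = i_e, i_i = i_i, tau_i = tau_i,
                 K = K, c = c, N = K / c, time_unit_ms = time_unit_ms),
            class = "mf_params")
}

#' @export
print.mf_params <- function(x, ...) {
  cat("Mean-field parameters (balanced E/I network)\n")
  cat(sprintf("  couplings: j_ee=%g j_ei=%g j_ie=%g j_ii=%g\n",
              x$j_ee, x$j_ei, x$j_ie, x$j_ii))
  cat(sprintf("  drives: i_e=%g i_i=%g   tau_i=%g\n", x$i_e, x$i_i, x$tau_i))
  cat(sprintf("  size: K=%g, c=%g (N=%g), 1 time unit = %g ms\n",
              x$K, x$c, x$N, x$time_unit_ms))
  invisible(x)
}

#' Short-term depression parameters
#'
#' Parameters of the phenomenological synaptic-efficacy dynamics
#' \deqn{dp/dt = (1 - p)/\tau_r - a(r_E)\,p/\tau_d,\qquad
#'       a(r) = m / (1 + e^{-\beta (r - \theta)}).}
#' Recovery acts on timescale `tau_r`, recruitment of depression on `tau_d`,
#' and recruitment is sigmoidal in the presynaptic excitatory activation with
#' half-maximum at the threshold `theta`.  One instance is used per depressing
#' pathway (E to E and E to I), identical except for `theta`.
#'
#' @param tau_r Recovery timescale (time units, > 0).
#' @param tau_d Depression timescale (time units, > 0).
#' @param m Maximal recruitment rate (dimensionless, >= 0).
#' @param beta Sigmoid gain.
#' @param theta Depression threshold in `r_E`, in \[0, 1\].
#'
#' @return An object of class `"stp_params"`.
#' @examples
#' pp <- stp_params(theta = 0.2)
#' plasticity_fixed_point(1, pp)  # depressed-state efficacy ~ 0.11
#' @export
stp_params <- function(tau_r = 40, tau_d = 10, m = 2, beta = 50, theta = 0.5) {
  stopifnot(tau_r > 0, tau_d > 0, m >= 0, theta >= 0, theta <= 1)
  structure(list(tau_r = tau_r, tau_d = tau_d, m = m, beta = beta,
                 theta = theta),
            class = "stp_params")
}

#' @export
print.stp_params <- function(x, ...) {
  cat(sprintf(
    "Short-term depression: tau_r=%g tau_d=%g m=%g beta=%g theta=%g\n",
    x$tau_r, x$tau_d, x$m, x$beta, x$theta))
  invisible(x)
}

#' Network state of the rate model
#'
#' @param r_e,r_i Population activations in \[0, 1\].
#' @param p_ee,p_ie Synaptic efficacies in (0, 1\].
#' @return Named numeric vector with components `r_e`, `r_i`, `p_ee`, `p_ie`.
#' @export
network_state <- function(r_e, r_i, p_ee = 1, p_ie = 1) {
  s <- c(r_e = r_e, r_i = r_i, p_ee = p_ee, p_ie = p_ie)
  if (any(s < 0) || any(s > 1))
    stop("state components must lie in [0, 1]", call. = FALSE)
  if (p_ee <= 0 || p_ie <= 0)
    stop("efficacies must be positive", call. = FALSE)
  s
}
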