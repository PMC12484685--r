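# Leaky integrate-and-fire E/I network with spike-recruited short-term
# depression (multiplicative) and facilitation (additive) on excitatory
# synapses, kick-evoked population events and input-current correlation
# analysis.

#' LIF neuron parameters
#'
#' Membrane constants of the leaky integrate-and-fire populations.  Voltages
#' are in threshold-normalised units (threshold 1, reset 0); resting
#' potentials are heterogeneous, drawn uniformly per neuron.
#'
#' @param tau_e,tau_i Membrane time constants (ms).
#' @param v_th,v_re Threshold and reset.
#' @param tau_ref Refractory period (ms).
#' @param mu_e,mu_i Length-2 vectors: uniform bounds of the resting
#'   potentials per population.
#' @param sigma_e,sigma_i White-noise intensities.
#' @return List of class `"neuron_params"`.
#' @export
neuron_params <- function(tau_e = 20, tau_i = 10, v_th = 1, v_re = 0,
                          tau_ref = 2, mu_e = c(0.8, 1.04),
                          mu_i = c(0.45, 0.7),
                          sigma_e = 0.17, sigma_i = 0.04) {
  stopifnot(v_re < v_th, tau_e > 0, tau_i > 0, tau_ref > 0,
            length(mu_e) == 2, length(mu_i) == 2,
            sigma_e >= 0, sigma_i >= 0)
  structure(list(tau_e = tau_e, tau_i = tau_i, v_th = v_th, v_re = v_re,
                 tau_ref = tau_ref, mu_e = mu_e, mu_i = mu_i,
                 sigma_e = sigma_e, sigma_i = sigma_i),
            class = "neuron_params")
}

#' Synapse parameters of the spiking network
#'
#' Connection probabilities, baseline strengths, double-exponential kernel
#' timescales per presynaptic class, and the short-term plasticity updates of
#' excitatory synapses: depression multiplies `D` by `d` per presynaptic
#' spike, facilitation adds `f` to `F`; both relax exponentially back to 1.
#' Inhibitory-presynaptic connections carry no plasticity.
#'
#' @param chi 2x2 connection probability matrix, rows = postsynaptic class
#'   (E, I), columns = presynaptic class.
#' @param jbar 2x2 baseline synaptic strengths (same layout; inhibitory
#'   columns negative).
#' @param tau_rise_e,tau_decay_e,tau_rise_i,tau_decay_i Kernel timescales
#'   (ms) per presynaptic class.
#' @param d_ee,f_ee,d_ie,f_ie Spike-recruited depression (in (0,1]) and
#'   facilitation (>= 0) per pathway (post class <- E).
#' @param tau_dep,tau_fac Recovery timescales of `D` and `F` (ms).
#' @return List of class `"synapse_params"`.
#' @export
synapse_params <- function(chi = matrix(0.2, 2, 2,
                                        dimnames = list(c("E", "I"),
                                                        c("E", "I"))),
                           jbar = NULL,
                           tau_rise_e = 1, tau_decay_e = 5,
                           tau_rise_i = 1, tau_decay_i = 8,
                           d_ee = 0.24, f_ee = 0.85,
                           d_ie = 0.24, f_ie = 0,
                           tau_dep = 150, tau_fac = 200) {
  if (is.null(jbar))
    jbar <- matrix(c(0.07, 0.135, -0.55, -0.45), 2, 2,
                   dimnames = list(c("E", "I"), c("E", "I")))
  stopifnot(all(chi >= 0), all(chi <= 1),
            d_ee > 0, d_ee <= 1, d_ie > 0, d_ie <= 1,
            f_ee >= 0, f_ie >= 0, tau_dep > 0, tau_fac > 0,
            tau_decay_e > tau_rise_e, tau_decay_i > tau_rise_i)
  structure(list(chi = chi, jbar = jbar,
                 tau_rise_e = tau_rise_e, tau_decay_e = tau_decay_e,
                 tau_rise_i = tau_rise_i, tau_decay_i = tau_decay_i,
                 d_ee = d_ee, f_ee = f_ee, d_ie = d_ie, f_ie = f_ie,
                 tau_dep = tau_dep, tau_fac = tau_fac),
            class = "synapse_params")
}

#' Named parameter profile for the spiking network
#'
#' Shipped default configuration reproducing the qualitative population-event
#' regimes (asynchronous ~1 Hz baseline; kick-evoked rhythmic events at low
#' `f_ie`, arrhythmic at intermediate, none at `f_ie = f_ee`).  All values
#' are package choices and are overridable; they are not measurements.
#'
#' @param N_E,N_I Population sizes.
#' @param f_ie Facilitation of the E-to-I pathway (the main experimental
#'   dial; `f_ie = f_ee` removes the effective-depression asymmetry).
#' @param ... Overrides passed to [neuron_params()] / [synapse_params()]
#'   (matched by name).
#' @return List with `N_E`, `N_I`, `np`, `sp`.
#' @export
spiking_profile <- function(N_E = 4000, N_I = 1000, f_ie = 0, ...) {
  dots <- list(...)
  np_names <- names(formals(neuron_params))
  sp_names <- names(formals(synapse_params))
  np <- do.call(neuron_params, dots[names(dots) %in% np_names])
  sp <- do.call(synapse_params,
                c(list(f_ie = f_ie), dots[names(dots) %in% sp_names]))
  list(N_E = N_E, N_I = N_I, np = np, sp = sp)
}

#' Build a random network realisation
#'
#' Independent Bernoulli adjacency per ordered (postsynaptic, presynaptic)
#' pair with probability `chi`, plus uniformly drawn resting potentials.
#' Stored in compressed form by presynaptic neuron, split by postsynaptic
#' class.  Reproducible given the seed.
#'
#' @param N_E,N_I Population sizes.
#' @param sp [synapse_params()].
#' @param np [neuron_params()].
#' @param seed Integer seed.
#' @return List of class `"spiking_net"`.
#' @export
build_network <- function(N_E, N_I, sp, np, seed = 1) {
  stopifnot(N_E >= 1, N_I >= 1)
  set.seed(seed)
  N <- N_E + N_I
  mu <- c(runif(N_E, np$mu_e[1], np$mu_e[2]),
          runif(N_I, np$mu_i[1], np$mu_i[2]))
  adjE <- vector("list", N)  # targets in E (0-based for C++)
  adjI <- vector("list", N)
  for (j in seq_len(N)) {
    pre <- if (j <= N_E) "E" else "I"
    kE <- rbinom(1, N_E, sp$chi["E", pre])
    kI <- rbinom(1, N_I, sp$chi["I", pre])
    adjE[[j]] <- if (kE > 0) sort(sample.int(N_E, kE)) - 1L else integer(0)
    adjI[[j]] <- if (kI > 0) N_E + sort(sample.int(N_I, kI)) - 1L
                 else integer(0)
  }
  lenE <- vapply(adjE, length, integer(1))
  lenI <- vapply(adjI, length, integer(1))
  structure(list(N_E = N_E, N_I = N_I,
                 adjE_ptr = c(0L, cumsum(lenE)),
                 adjE_idx = unlist(adjE, use.names = FALSE),
                 adjI_ptr = c(0L, cumsum(lenI)),
                 adjI_idx = unlist(adjI, use.names = FALSE),
                 mu = mu, np = np, sp = sp, seed = seed),
            class = "spiking_net")
}

#' @export
print.spiking_net <- function(x, ...) {
  cat(sprintf("Spiking network: N_E=%d N_I=%d, %d synapses (seed %d)\n",
              x$N_E, x$N_I,
              length(x$adjE_idx) + length(x$adjI_idx), x$seed))
  invisible(x)
}

#' STP update at a presynaptic spike
#'
#' Multiplicative depression and additive facilitation:
#' `D -> D d`, `F -> F + f`.
#'
#' @param factors List with `D` and `F`.
#' @param d,f Spike-recruited depression (in (0,1]) and facilitation (>= 0).
#' @return Updated factors list.
#' @export
stp_on_spike <- function(factors, d, f) {
  stopifnot(d > 0, d <= 1, f >= 0)
  list(D = factors$D * d, F = factors$F + f)
}

#' Exponential STP recovery between spikes
#'
#' Exact relaxation of both factors towards 1 over `dt`; composition over
#' split intervals equals one step over their sum.
#'
#' @param factors List with `D` and `F`.
#' @param dt Elapsed time (ms, >= 0).
#' @param tau_dep,tau_fac Recovery timescales (ms).
#' @return Updated factors list.
#' @export
stp_decay <- function(factors, dt, tau_dep, tau_fac) {
  stopifnot(dt >= 0)
  list(D = 1 + (factors$D - 1) * exp(-dt / tau_dep),
       F = 1 + (factors$F - 1) * exp(-dt / tau_fac))
}

#' Double-exponential synaptic kernel
#'
#' \eqn{S(t) = (e^{-t/\tau_d} - e^{-t/\tau_r}) / (\tau_d - \tau_r)} for
#' `t >= 0`; non-negative and integrating to one.  Falls back to the alpha
#' function \eqn{t e^{-t/\tau} / \tau^2} when the timescales coincide.
#'
#' @param t Time(s) since the presynaptic spike (ms, >= 0).
#' @param tau_rise,tau_decay Kernel timescales (ms).
#' @return Kernel value(s) (1/ms).
#' @export
synaptic_kernel <- function(t, tau_rise, tau_decay) {
  stopifnot(all(t >= 0), tau_rise > 0, tau_decay >= tau_rise)
  if (tau_decay == tau_rise)
    return(t * exp(-t / tau_decay) / tau_decay^2)
  (exp(-t / tau_decay) - exp(-t / tau_rise)) / (tau_decay - tau_rise)
}

#' Simulate the spiking network
#'
#' Euler-Maruyama integration (default step 0.1 ms) of all membranes with
#' threshold-reset spiking, refractoriness, double-exponential synaptic
#' kernels scaled by `Jbar * D * F` at the presynaptic spike time, and an
#' optional external kick.  Per-neuron excitatory and inhibitory input
#' currents can be recorded separately for correlation analysis.
#'
#' @param net A [build_network()] result.
#' @param T_ms Simulated time (ms).
#' @param seed Integer seed.
#' @param kick Optional list `list(idx=, amp=, on=, off=)` (1-based neuron
#'   indices; see [kick_protocol()]).
#' @param dt Time step (ms).
#' @param record_idx Neuron indices whose input currents are recorded.
#' @param record_stride Recording stride in steps.
#' @param v0 Initial membrane potentials (defaults to the resting values).
#' @param max_mean_rate_hz Abort (with an error) if the running mean
#'   population rate exceeds this value: guards against runaway activity.
#' @return Object of class `"lif_sim"`: `spikes` (data frame `id`, `t_ms`),
#'   `currents` (or `NULL`), sizes and settings.
#' @export
simulate_spiking <- function(net, T_ms, seed = 1, kick = NULL, dt = 0.1,
                             record_idx = integer(0), record_stride = 10L,
                             v0 = NULL, max_mean_rate_hz = 150) {
  stopifnot(T_ms > 0, dt > 0)
  np <- net$np; sp <- net$sp
  if (is.null(v0)) v0 <- net$mu
  if (is.null(kick)) kick <- list(idx = integer(0), amp = numeric(0),
                                  on = 0, off = 0)
  set.seed(seed)
  res <- lif_sim_cpp(net$N_E, net$N_I,
                     net$adjE_ptr, net$adjE_idx, net$adjI_ptr, net$adjI_idx,
                     net$mu,
                     np$tau_e, np$tau_i, np$v_th, np$v_re, np$tau_ref,
                     np$sigma_e, np$sigma_i,
                     sp$tau_rise_e, sp$tau_decay_e,
                     sp$tau_rise_i, sp$tau_decay_i,
                     sp$jbar["E", "E"], sp$jbar["E", "I"],
                     sp$jbar["I", "E"], sp$jbar["I", "I"],
                     sp$d_ee, sp$f_ee, sp$d_ie, sp$f_ie,
                     sp$tau_dep, sp$tau_fac,
                     as.integer(kick$idx) - 1L, as.numeric(kick$amp),
                     kick$on, kick$off,
                     T_ms, dt,
                     as.integer(record_idx) - 1L, as.integer(record_stride),
                     v0, max_mean_rate_hz)
  currents <- res$currents
  if (!is.null(currents)) currents$idx <- as.integer(record_idx)
  structure(list(spikes = data.frame(id = res$id, t_ms = res$time),
                 currents = currents, N_E = net$N_E, N_I = net$N_I,
                 T_ms = T_ms, dt = dt, seed = seed,
                 kick = if (length(kick$idx)) kick else NULL),
            class = "lif_sim")
}

#' @export
print.lif_sim <- function(x, ...) {
  e_sp <- sum(x$spikes$id <= x$N_E)
  cat(sprintf(
    "LIF simulation: %g ms, N_E=%d N_I=%d; %d spikes (E rate %.2f Hz)\n",
    x$T_ms, x$N_E, x$N_I, nrow(x$spikes),
    e_sp / x$N_E / (x$T_ms / 1000)))
  invisible(x)
}

#' Select kick targets from a baseline run
#'
#' The kicked subset is the `n` excitatory neurons with the highest average
#' firing rate in a baseline (un-kicked) simulation.
#'
#' @param baseline A `lif_sim` from an un-kicked run.
#' @param n Number of neurons (default `N_E / 20`).
#' @return Integer vector of neuron indices.
#' @export
select_kick_targets <- function(baseline, n = baseline$N_E %/% 20) {
  sp <- baseline$spikes
  counts <- tabulate(sp$id[sp$id <= baseline$N_E], nbins = baseline$N_E)
  order(counts, decreasing = TRUE)[seq_len(n)]
}

#' Kick protocol
#'
#' Square-pulse external input of 80 ms to a chosen excitatory subset, with
#' per-neuron amplitudes drawn from a normal distribution (mean
#' `17.1 / tau_e`, variance 5e-2).
#'
#' @param idx Kicked neuron indices (excitatory).
#' @param t_on Kick onset (ms).
#' @param duration_ms Kick duration (default 80 ms).
#' @param tau_e Excitatory membrane constant (scales the mean amplitude).
#' @param mean_amp,var_amp Amplitude distribution parameters.
#' @param seed Integer seed for the amplitude draw.
#' @return List `idx`, `amp`, `on`, `off` for [simulate_spiking()].
#' @export
kick_protocol <- function(idx, t_on, duration_ms = 80, tau_e = 20,
                          mean_amp = 17.1 / tau_e, var_amp = 5e-2,
                          seed = 1) {
  set.seed(seed)
  list(idx = idx, amp = rnorm(length(idx), mean_amp, sqrt(var_amp)),
       on = t_on, off = t_on + duration_ms)
}

#' Binned population firing rate
#'
#' Population rate in Hz over the non-excluded neurons of one population.
#'
#' @param sim A `lif_sim` (or data frame of spikes with `id`, `t_ms`).
#' @param pop `"E"` or `"I"`.
#' @param exclude Neuron indices excluded from the average (e.g. kicked).
#' @param bin_ms Bin width (ms).
#' @param N_E,N_I,T_ms Sizes and duration (taken from `sim` if available).
#' @return Data frame `t_ms` (bin centres), `rate_hz`.
#' @export
population_rate <- function(sim, pop = "E", exclude = integer(0),
                            bin_ms = 10, N_E = sim$N_E, N_I = sim$N_I,
                            T_ms = sim$T_ms) {
  spikes <- if (inherits(sim, "lif_sim")) sim$spikes else sim
  ids <- if (pop == "E") spikes$id <= N_E else spikes$id > N_E
  keep <- ids & !(spikes$id %in% exclude)
  n_excl <- if (pop == "E") sum(exclude >= 1 & exclude <= N_E)
            else sum(exclude > N_E)
  n_pop <- (if (pop == "E") N_E else N_I) - n_excl
  breaks <- seq(0, T_ms, by = bin_ms)
  if (breaks[length(breaks)] < T_ms) breaks <- c(breaks, T_ms)
  cnt <- graphics::hist(spikes$t_ms[keep], breaks = breaks,
                        plot = FALSE)$counts
  widths <- diff(breaks)
  data.frame(t_ms = (breaks[-length(breaks)] + breaks[-1]) / 2,
             rate_hz = cnt / n_pop / (widths / 1000))
}

#' Five-pulse synaptic response ratio
#'
#' Drives a single plastic synapse with five equally spaced presynaptic
#' spikes into a passive (leak-only) postsynaptic membrane from rest and
#' returns the ratio of the fifth to the first response height.  Each
#' response height is measured against the superposed continuation of the
#' earlier responses (the trace with that pulse omitted), the standard
#' peak-to-projected-baseline measurement; a static synapse gives exactly 1.
#'
#' @param sp [synapse_params()].
#' @param rate_hz Pulse rate (> 0).
#' @param pathway `"EE"` or `"IE"` (postsynaptic class, presynaptic E).
#' @param tau_m Postsynaptic membrane constant (ms).
#' @param dt Integration step (ms).
#' @return Ratio (5th PSP peak) / (1st PSP peak).
#' @export
five_pulse_ratio <- function(sp, rate_hz, pathway = c("EE", "IE"),
                             tau_m = 20, dt = 0.02) {
  stopifnot(rate_hz > 0)
  pathway <- match.arg(pathway)
  d <- if (pathway == "EE") sp$d_ee else sp$d_ie
  f <- if (pathway == "EE") sp$f_ee else sp$f_ie
  isi <- 1000 / rate_hz
  spike_t <- (0:4) * isi
  # synaptic efficacy at each spike time (D F just before the update)
  fac <- list(D = 1, F = 1)
  w <- numeric(5)
  for (k in 1:5) {
    if (k > 1) fac <- stp_decay(fac, isi, sp$tau_dep, sp$tau_fac)
    w[k] <- fac$D * fac$F
    fac <- stp_on_spike(fac, d, f)
  }
  T_end <- spike_t[5] + 6 * max(sp$tau_decay_e, tau_m)
  tt <- seq(0, T_end, by = dt)
  membrane <- function(weights) {
    drive <- numeric(length(tt))
    for (k in seq_along(weights)) {
      if (weights[k] == 0) next
      after <- tt >= spike_t[k]
      drive[after] <- drive[after] +
        weights[k] * synaptic_kernel(tt[after] - spike_t[k],
                                     sp$tau_rise_e, sp$tau_decay_e)
    }
    v <- numeric(length(tt))
    for (i in 2:length(tt))
      v[i] <- v[i - 1] + dt * (-v[i - 1] / tau_m + drive[i - 1])
    v
  }
  v_all <- membrane(w)
  height <- function(k) {
    w_minus <- w
    w_minus[k] <- 0
    max(v_all - membrane(w_minus))
  }
  height(5) / height(1)
}

#' Pairwise correlations of synaptic input currents
#'
#' Pearson correlations of same-type input currents across recorded neuron
#' pairs: excitatory inputs (EE), inhibitory inputs (II) and the summed
#' composite input, averaged over all pairs, computed separately inside and
#' outside population events.  In the balanced asynchronous state shared
#' inhibition tracks and cancels shared excitation, so the composite
#' correlation is smaller than either same-type correlation.
#'
#' @param currents The `currents` component of a `lif_sim` (record some
#'   neurons via `record_idx`).
#' @param event_mask Logical vector over recorded time points (`TRUE` inside
#'   events); `NULL` treats the whole recording as non-event.
#' @return Data frame with columns `type` (EE, II, composite), `period`
#'   (event / nonevent), `correlation`, `n_pairs`.
#' @export
current_correlations <- function(currents, event_mask = NULL) {
  ie <- currents$i_exc
  ii <- currents$i_inh
  n <- ncol(ie)
  if (n < 2L) stop("need input currents for at least 2 neurons",
                   call. = FALSE)
  if (is.null(event_mask)) event_mask <- rep(FALSE, nrow(ie))
  comp <- ie + ii
  mean_pair_cor <- function(m, mask) {
    if (sum(mask) < 3L) return(c(NA_real_, 0))
    sub <- m[mask, , drop = FALSE]
    ok <- apply(sub, 2, sd) > 0
    if (sum(ok) < 2L) {
      warning("constant traces excluded from correlation", call. = FALSE)
      return(c(NA_real_, 0))
    }
    cm <- cor(sub[, ok, drop = FALSE])
    vals <- cm[upper.tri(cm)]
    c(mean(vals), length(vals))
  }
  rows <- list()
  for (period in c("event", "nonevent")) {
    mask <- if (period == "event") event_mask else !event_mask
    for (type in c("EE", "II", "composite")) {
      m <- switch(type, EE = ie, II = ii, composite = comp)
      r <- mean_pair_cor(m, mask)
      rows[[length(rows) + 1L]] <-
        data.frame(type = type, period = period,
                   correlation = r[1], n_pairs = r[2])
    }
  }
  do.call(rbind, rows)
}

#' Kick-evoked population-event experiment
#'
#' Runs the full stimulation protocol: an un-kicked baseline simulation to
#' select the highest-rate excitatory neurons, then a kicked run with the
#' same network structure.  Returns the binned population rate of the
#' non-kicked excitatory neurons, the post-kick excess-rate energy, and the
#' spectrum-based rhythm classification of the post-kick response.
#'
#' @param f_ie Facilitation of the E-to-I pathway.
#' @param seed Integer seed (baseline and kicked runs derive from it).
#' @param N_E,N_I Population sizes.
#' @param baseline_T Baseline duration used for target selection (ms).
#' @param t_on Kick onset in the kicked run (ms).
#' @param T_post Analysis window after kick offset (ms).
#' @param band Frequency band searched for a post-kick rhythm (Hz).
#' @param ... Overrides forwarded to [spiking_profile()].
#' @return List of class `"kick_response"`: `baseline_hz`, `rate` (data
#'   frame), `energy` (excess Hz s after kick offset), `peak_hz`
#'   (post-kick spectral peak or `NA`), `n_bursts` (distinct post-kick
#'   population bursts rising at least 2 Hz above baseline; three or more
#'   indicate a rhythmic event), `post_max_hz`.
#' @export
kick_response <- function(f_ie, seed = 1, N_E = 4000, N_I = 1000,
                          baseline_T = 4000, t_on = 1500, T_post = 1400,
                          band = c(2, 30), ...) {
  prof <- spiking_profile(N_E = N_E, N_I = N_I, f_ie = f_ie, ...)
  net <- build_network(prof$N_E, prof$N_I, prof$sp, prof$np, seed = seed)
  base <- simulate_spiking(net, T_ms = baseline_T, seed = seed + 1L)
  sp_b <- base$spikes[base$spikes$t_ms > 1000, ]
  baseline_hz <- sum(sp_b$id <= net$N_E) / net$N_E /
    ((baseline_T - 1000) / 1000)
  targets <- select_kick_targets(base)
  kick <- kick_protocol(targets, t_on = t_on, tau_e = prof$np$tau_e,
                        seed = seed + 2L)
  T_ms <- kick$off + T_post
  sim <- simulate_spiking(net, T_ms = T_ms, seed = seed + 3L, kick = kick)
  rate <- population_rate(sim, exclude = targets, bin_ms = 10)
  pre <- mean(rate$rate_hz[rate$t_ms > 500 & rate$t_ms < t_on])
  post <- rate$rate_hz[rate$t_ms >= kick$off & rate$t_ms <= T_ms]
  energy <- sum(pmax(post - pre, 0)) * 0.01
  spec <- welch_psd(post - mean(post), fs = 100,
                    seg_s = min(1, length(post) / 100), unit_area = TRUE)
  pk <- classify_peak(spec, band = band, flat_factor = 0)
  # population bursts: distinct bins of the post-kick rate rising well
  # above the pre-kick baseline; a rhythmic event repeats them
  hot <- which(post >= pre + 2)
  pk_idx <- hot[c(TRUE, diff(hot) >= 3L)]  # distinct if >= 30 ms apart
  structure(list(baseline_hz = baseline_hz, rate = rate, energy = energy,
                 peak_hz = pk$peak_hz, post_max_hz = max(post),
                 n_bursts = length(pk_idx),
                 pre_hz = pre, f_ie = f_ie, seed = seed),
            class = "kick_response")
}

#' @export
print.kick_response <- function(x, ...) {
  cat(sprintf(
    "Kick response (f_ie=%.2f): baseline %.2f Hz, excess energy %.2f Hz*s, post peak %.1f Hz, %s\n",
    x$f_ie, x$baseline_hz, x$energy, x$post_max_hz,
    sprintf("%d burst(s)", x$n_bursts)))
  invisible(x)
}
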