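#' Birth-death transition rates of the finite-size network
#'
#' The four propensities of the two-population birth-death master equation at
#' a given state: excitatory birth \eqn{N_E f(\sqrt{N_g}(j_{EE} p_{EE} n/N_E -
#' j_{EI} m/N_I + I_E))}, excitatory death \eqn{n}, inhibitory birth
#' \eqn{(N_I/\tau_I) f(\cdot)} and inhibitory death \eqn{m/\tau_I}.  Birth
#' rates are forced to zero at the population ceiling.
#'
#' @param n_e,n_i Active counts (0 <= n <= N).
#' @param p_ee,p_ie Current synaptic efficacies.
#' @param mp [mf_params()].
#' @param N_E,N_I Population sizes; default both `mp$K` (the finite-size
#'   noise scale), while the transfer gain stays at `sqrt(mp$N)`.
#' @param gain Transfer gain; defaults to `sqrt(mp$N)`.
#' @return Named vector `(e_birth, e_death, i_birth, i_death)`.
#' @export
transition_rates <- function(n_e, n_i, p_ee, p_ie, mp,
                             N_E = mp$K, N_I = mp$K, gain = sqrt(mp$N)) {
  stopifnot(n_e >= 0, n_e <= N_E, n_i >= 0, n_i <= N_I)
  r_e <- n_e / N_E
  r_i <- n_i / N_I
  e_birth <- if (n_e >= N_E) 0 else
    N_E * transfer(gain * (mp$j_ee * p_ee * r_e - mp$j_ei * r_i + mp$i_e))
  i_birth <- if (n_i >= N_I) 0 else
    (N_I / mp$tau_i) * transfer(gain * (mp$j_ie * p_ie * r_e - mp$j_ii * r_i + mp$i_i))
  c(e_birth = e_birth, e_death = n_e,
    i_birth = i_birth, i_death = n_i / mp$tau_i)
}

#' Hybrid Gillespie simulation of the finite-size network
#'
#' Exact stochastic simulation of the birth-death Markov process with the
#' synaptic efficacies treated as piecewise-deterministic slow variables:
#' propensities are frozen between jumps, the waiting time is exponential in
#' the summed propensity, and the efficacies advance by their exact
#' exponential update at the frozen excitatory activation.  Population sizes
#' set the finite-size fluctuation scale \eqn{1/\sqrt{N_E}} and default to
#' the connection count `K`; the deterministic transfer gain is
#' \eqn{\sqrt{N}} with `N = K/c` as in the rate model.
#'
#' @param mp [mf_params()].
#' @param pp_ee,pp_ie [stp_params()] for the two depressing pathways.
#' @param T Simulated time (model units; 100 units = 1 s with defaults).
#' @param seed Integer seed (runs with equal seeds are identical).
#' @param N_E,N_I Population sizes.
#' @param dt_out Uniform sampling step of the returned trace.
#' @param init Optional list `list(n_e=, n_i=, p_ee=, p_ie=)`; defaults to a
#'   low-activity state with efficacies at their fixed point
#'   ([plasticity_fixed_point()]).
#' @param record_path Also return the full jump path (memory scales with the
#'   jump count; use for short runs).
#' @param freeze_plasticity Hold the efficacies at their initial values
#'   (pure birth-death process).
#' @return Object of class `"markov_sim"`: list with `grid` (data frame
#'   `t, r_e, r_i, p_ee, p_ie`), `path` (or `NULL`), `n_jumps`, and the
#'   simulation settings.
#' @examples
#' mp <- mf_params()
#' sim <- simulate_markov(mp, stp_params(theta = 0.5), stp_params(theta = 0.2),
#'                        T = 200, seed = 1)
#' @export
simulate_markov <- function(mp, pp_ee, pp_ie, T, seed,
                            N_E = mp$K, N_I = mp$K, dt_out = 0.1,
                            init = NULL, record_path = FALSE,
                            freeze_plasticity = FALSE) {
  stopifnot(T > 0, dt_out > 0)
  if (!identical(pp_ee[c("tau_r", "tau_d", "m", "beta")],
                 pp_ie[c("tau_r", "tau_d", "m", "beta")]))
    stop("pathways must share tau_r, tau_d, m, beta (thresholds may differ)",
         call. = FALSE)
  if (is.null(init)) {
    r_e0 <- 0.05
    r_i0 <- 0.08
    init <- list(n_e = round(r_e0 * N_E), n_i = round(r_i0 * N_I),
                 p_ee = plasticity_fixed_point(r_e0, pp_ee),
                 p_ie = plasticity_fixed_point(r_e0, pp_ie))
  }
  set.seed(seed)
  res <- markov_sim_cpp(init$n_e, init$n_i, N_E, N_I, sqrt(mp$N),
                        mp$j_ee, mp$j_ei, mp$j_ie, mp$j_ii,
                        mp$i_e, mp$i_i, mp$tau_i,
                        pp_ee$tau_r, pp_ee$tau_d, pp_ee$m, pp_ee$beta,
                        pp_ee$theta, pp_ie$theta,
                        init$p_ee, init$p_ie,
                        T, dt_out, record_path, freeze_plasticity,
                        max_jumps = 5e8)
  grid <- data.frame(t = res$t, r_e = res$r_e, r_i = res$r_i,
                     p_ee = res$p_ee, p_ie = res$p_ie)
  structure(list(grid = grid, path = res$path, n_jumps = res$n_jumps,
                 N_E = N_E, N_I = N_I, seed = seed, dt_out = dt_out,
                 time_unit_ms = mp$time_unit_ms),
            class = "markov_sim")
}

#' @export
print.markov_sim <- function(x, ...) {
  cat(sprintf(
    "Birth-death simulation: N_E=%d N_I=%d, %.0f jumps over %g time units\n",
    x$N_E, x$N_I, x$n_jumps, max(x$grid$t)))
  cat(sprintf("  r_e: mean %.4f, max %.4f (seed %d)\n",
              mean(x$grid$r_e), max(x$grid$r_e), x$seed))
  invisible(x)
}

#' @export
plot.markov_sim <- function(x, ...) {
  plot(x$grid$t * x$time_unit_ms / 1000, x$grid$r_e, type = "s",
       xlab = "time (s)", ylab = "r_E", col = "firebrick", ...)
  invisible(x)
}

#' Resample a jump path onto a uniform grid
#'
#' Sample-and-hold resampling of a recorded jump path (see
#' [simulate_markov()] with `record_path = TRUE`) onto a uniform grid, for
#' spectral analysis.  Values at a grid time are those of the most recent
#' jump at or before it.
#'
#' @param path List with components `t`, `n_e`, `n_i`, `p_ee`, `p_ie`.
#' @param dt Grid step (> 0, model units).
#' @param N_E,N_I Population sizes used to normalise counts to activations.
#' @return Data frame `t, r_e, r_i, p_ee, p_ie` on the uniform grid.
#' @export
resample_uniform <- function(path, dt, N_E, N_I) {
  stopifnot(dt > 0)
  if (is.null(path) || length(path$t) == 0L)
    stop("empty jump path", call. = FALSE)
  tg <- seq(0, max(path$t), by = dt)
  idx <- findInterval(tg, path$t)
  idx[idx == 0L] <- 1L
  data.frame(t = tg,
             r_e = path$n_e[idx] / N_E,
             r_i = path$n_i[idx] / N_I,
             p_ee = path$p_ee[idx],
             p_ie = path$p_ie[idx])
}

#' Population-event statistics from a rate trace
#'
#' Events are threshold upcrossings of `r_e` separated by at least
#' `min_separation`.  Returns event times, inter-event intervals, their
#' coefficient of variation (1 for a Poisson process of rare events) and the
#' event rate per time unit.
#'
#' @param x A `markov_sim`, or a data frame with columns `t` and `r_e`.
#' @param threshold Upcrossing level of `r_e`.
#' @param min_separation Minimum time between distinct events (model units).
#' @return Object of class `"event_stats"`: list with `event_times`,
#'   `intervals`, `interval_cv`, `rate_per_time`, `n_events`, `duration`.
#' @export
detect_population_events_rate <- function(x, threshold = 0.5,
                                          min_separation = 50) {
  g <- if (inherits(x, "markov_sim")) x$grid else x
  above <- g$r_e >= threshold
  up <- which(diff(above) == 1L) + 1L
  times <- g$t[up]
  if (length(times)) {
    keep <- c(TRUE, diff(times) >= min_separation)
    # enforce separation sequentially (diff alone can chain short gaps)
    sel <- numeric(0)
    last <- -Inf
    for (tt in times) {
      if (tt - last >= min_separation) {
        sel <- c(sel, tt)
        last <- tt
      }
    }
    times <- sel
  }
  iv <- diff(times)
  cv <- if (length(iv) >= 2L) sd(iv) / mean(iv) else NA_real_
  structure(list(event_times = times, intervals = iv, interval_cv = cv,
                 rate_per_time = length(times) / max(g$t),
                 n_events = length(times), duration = max(g$t)),
            class = "event_stats")
}

#' @export
print.event_stats <- function(x, ...) {
  cat(sprintf("%d population events in %g time units (rate %.3g per unit)\n",
              x$n_events, x$duration, x$rate_per_time))
  if (!is.na(x$interval_cv))
    cat(sprintf("  inter-event interval CV: %.2f\n", x$interval_cv))
  invisible(x)
}

# extract event epochs (index ranges) from a rate trace: upcrossing minus a
# lead-in, until r_e has returned below `quiet` level
event_epochs <- function(g, threshold = 0.5, min_separation = 50,
                         pre = 20, quiet = 0.1, max_len = 300) {
  ev <- detect_population_events_rate(g, threshold, min_separation)
  if (inherits(g, "markov_sim")) g <- g$grid
  dt <- g$t[2] - g$t[1]
  lapply(ev$event_times, function(t0) {
    i0 <- max(1L, round((t0 - pre) / dt) + 1L)
    after <- which(g$t > t0 & g$r_e < quiet)
    i1 <- if (length(after)) after[1] else nrow(g)
    i1 <- min(i1 + round(pre / dt), nrow(g), i0 + round(max_len / dt))
    c(i0, i1)
  })
}

#' Averaged within-event power spectrum of the excitatory rate
#'
#' Extracts event epochs from a uniformly sampled simulation (upcrossing of
#' `threshold`, padded backwards by `pre` time units, ending once `r_e` has
#' returned below the quiescent level), converts to real time via
#' `time_unit_ms`, computes a Welch spectrum per event (unit area), and
#' averages across events with max-one normalisation.
#'
#' Rhythmicity of the events is judged by cycle repetition: within an
#' epoch, each upcrossing of `threshold` after a reset below `quiet` counts
#' as one population surge, and the event set is rhythmic when events carry
#' at least two surges on average.  In these rate traces the within-event
#' oscillation swings over the full activity range, so envelope power and
#' rhythm power have the same magnitude and a spectral-shape criterion
#' alone cannot separate them.  For rhythmic event sets `peak_hz` is the
#' in-band (1-20 Hz) maximum of the averaged spectrum; otherwise `NA`.
#'
#' @param x A `markov_sim` object (or data frame with `t`, `r_e`).
#' @param time_unit_ms Real milliseconds per model time unit.
#' @param threshold,min_separation,pre,quiet See [detect_population_events_rate()].
#' @param min_epoch_s Events shorter than this are skipped.
#' @param seg_s Welch segment length (seconds); short segments let the
#'   per-segment linear detrend absorb part of the slow event envelope.
#' @param band Frequency band (Hz) searched for the spectral peak.
#' @param min_cycles Mean surges per event required to call the set
#'   rhythmic.
#' @param reset Activity level below which the surge detector re-arms
#'   (oscillation troughs within an event dip below this level; a simple
#'   single-hump excursion never does).
#' @return Object of class `"event_spectrum"`: list with `frequency_hz`,
#'   `power` (max 1), `n_events`, `mean_cycles`, `cycle_rate_hz` (from the
#'   mean intra-event surge interval), `peak_hz`.
#' @export
markov_event_spectra <- function(x, time_unit_ms = 10, threshold = 0.5,
                                 min_separation = 50, pre = 20, quiet = 0.1,
                                 min_epoch_s = 0.25, seg_s = 0.5,
                                 band = c(1, 20), min_cycles = 2,
                                 reset = 0.3) {
  g <- if (inherits(x, "markov_sim")) x$grid else x
  if (inherits(x, "markov_sim")) time_unit_ms <- x$time_unit_ms
  eps <- event_epochs(g, threshold, min_separation, pre, quiet)
  dt_s <- (g$t[2] - g$t[1]) * time_unit_ms / 1000
  fs <- 1 / dt_s
  specs <- list()
  cycles <- integer(0)
  cycle_iv <- numeric(0)   # intra-event surge intervals (s)
  for (ep in eps) {
    xseg <- g$r_e[ep[1]:ep[2]]
    if (length(xseg) * dt_s < min_epoch_s) next
    specs[[length(specs) + 1L]] <-
      welch_psd(xseg, fs, seg_s = min(length(xseg) * dt_s, seg_s),
                unit_area = TRUE)
    # count surges: threshold upcrossings with a reset below `reset`
    armed <- TRUE
    ups <- numeric(0)
    for (i in seq_along(xseg)) {
      if (armed && xseg[i] >= threshold) {
        ups <- c(ups, i)
        armed <- FALSE
      } else if (!armed && xseg[i] < reset) {
        armed <- TRUE
      }
    }
    cycles <- c(cycles, length(ups))
    if (length(ups) > 1L) cycle_iv <- c(cycle_iv, diff(ups) * dt_s)
  }
  if (!length(specs))
    return(structure(list(frequency_hz = numeric(0), power = numeric(0),
                          n_events = 0L, mean_cycles = NA_real_,
                          cycle_rate_hz = NA_real_, peak_hz = NA_real_),
                     class = "event_spectrum"))
  fgrid <- specs[[1]]$frequency_hz
  acc <- rowMeans(vapply(specs, function(s)
    approx(s$frequency_hz, s$power, fgrid, rule = 2)$y,
    numeric(length(fgrid))))
  pow <- acc / max(acc)
  mean_cycles <- mean(cycles)
  in_band <- which(fgrid >= band[1] & fgrid <= band[2])
  peak_hz <- if (mean_cycles >= min_cycles)
    fgrid[in_band][which.max(pow[in_band])] else NA_real_
  structure(list(frequency_hz = fgrid, power = pow,
                 n_events = length(specs), mean_cycles = mean_cycles,
                 cycle_rate_hz = if (length(cycle_iv)) 1 / mean(cycle_iv)
                                 else NA_real_,
                 peak_hz = peak_hz),
            class = "event_spectrum")
}

#' Pool within-event spectra across simulation chunks
#'
#' Event-count-weighted average of `event_spectrum` objects from independent
#' runs, re-applying the rhythmicity rule to the pooled events.
#'
#' @param spectra List of objects returned by [markov_event_spectra()].
#' @param band,min_cycles As in [markov_event_spectra()].
#' @return A pooled `"event_spectrum"` object.
#' @export
combine_event_spectra <- function(spectra, band = c(1, 20), min_cycles = 2) {
  ok <- vapply(spectra, function(s) s$n_events > 0, logical(1))
  spectra <- spectra[ok]
  if (!length(spectra))
    return(structure(list(frequency_hz = numeric(0), power = numeric(0),
                          n_events = 0L, mean_cycles = NA_real_,
                          cycle_rate_hz = NA_real_, peak_hz = NA_real_),
                     class = "event_spectrum"))
  fgrid <- spectra[[1]]$frequency_hz
  wts <- vapply(spectra, function(s) s$n_events, integer(1))
  pows <- vapply(spectra, function(s)
    approx(s$frequency_hz, s$power, fgrid, rule = 2)$y,
    numeric(length(fgrid)))
  pow <- as.vector(pows %*% wts) / sum(wts)
  pow <- pow / max(pow)
  mean_cycles <- sum(vapply(spectra, function(s) s$mean_cycles, numeric(1)) *
                       wts) / sum(wts)
  in_band <- which(fgrid >= band[1] & fgrid <= band[2])
  peak_hz <- if (mean_cycles >= min_cycles)
    fgrid[in_band][which.max(pow[in_band])] else NA_real_
  structure(list(frequency_hz = fgrid, power = pow,
                 n_events = sum(wts), mean_cycles = mean_cycles,
                 cycle_rate_hz = NA_real_, peak_hz = peak_hz),
            class = "event_spectrum")
}

#' @export
print.event_spectrum <- function(x, ...) {
  cat(sprintf("Averaged spectrum over %d event(s)", x$n_events))
  if (!is.null(x$peak_hz) && !is.na(x$peak_hz))
    cat(sprintf("; peak at %.2f Hz\n", x$peak_hz))
  else cat("; no qualifying peak\n")
  invisible(x)
}
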