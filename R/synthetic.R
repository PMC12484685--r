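# Surrogate intracellular traces with known ground truth: mean-reverting
# noisy baseline with slow drift, sporadic rise-decay events, and an optional
# within-event rhythm.  Stands in for non-deposited slice recordings; only
# the statistical structure needed to exercise the analysis pipeline is
# emulated.

#' Specification of a synthetic recording
#'
#' @param duration_s Recording length (seconds).
#' @param sampling_hz Sampling rate.
#' @param units `"nA"` (voltage clamp) or `"mV"` (current clamp).
#' @param drift_amp Amplitude of the slow baseline drift (trace units).
#' @param drift_period_s Timescale of the drift.
#' @param noise_sd Standard deviation of the mean-reverting background noise.
#' @param noise_tau_s Correlation time of the background noise.
#' @param event_rate Poisson event rate per second.
#' @param amp_range Event amplitude range (uniform); defaults to 0.15-0.5 nA
#'   or 5-20 mV by units.
#' @param rise_s,decay_s Event envelope timescales (difference of
#'   exponentials), giving excursions lasting hundreds of milliseconds.
#' @param rhythm_fraction Fraction of events carrying a within-event rhythm.
#' @param rhythm_range_hz Rhythm frequency range.  The rhythm frequency is a
#'   recording-site (slice) property: it is drawn once per trace and shared
#'   by all rhythmic events, with per-event jitter `rhythm_jitter_hz`.
#' @param rhythm_jitter_hz SD of the per-event wobble around the slice
#'   frequency.
#' @param mod_depth Modulation depth of the rhythm in (0, 1].
#' @param seed Integer seed.
#' @return List of class `"synth_spec"`.
#' @export
synth_spec <- function(duration_s = 60, sampling_hz = 1000,
                       units = c("nA", "mV"),
                       drift_amp = NULL, drift_period_s = 20,
                       noise_sd = NULL, noise_tau_s = 0.1,
                       event_rate = 0.2, amp_range = NULL,
                       rise_s = 0.05, decay_s = 0.2,
                       rhythm_fraction = 1 / 3,
                       rhythm_range_hz = c(2, 12),
                       rhythm_jitter_hz = 0.2, mod_depth = 0.7,
                       seed = 1) {
  units <- match.arg(units)
  scale <- if (units == "nA") 1 else 100 / 3  # 0.15 nA ~ 5 mV equivalence
  if (is.null(amp_range)) amp_range <- c(0.15, 0.5) * scale
  if (is.null(noise_sd)) noise_sd <- 0.03 * scale
  if (is.null(drift_amp)) drift_amp <- 0.05 * scale
  stopifnot(duration_s > 0, sampling_hz > 0, event_rate >= 0,
            rhythm_fraction >= 0, rhythm_fraction <= 1,
            mod_depth >= 0, mod_depth <= 1, decay_s > rise_s)
  structure(list(duration_s = duration_s, sampling_hz = sampling_hz,
                 units = units, drift_amp = drift_amp,
                 drift_period_s = drift_period_s, noise_sd = noise_sd,
                 noise_tau_s = noise_tau_s, event_rate = event_rate,
                 amp_range = amp_range, rise_s = rise_s, decay_s = decay_s,
                 rhythm_fraction = rhythm_fraction,
                 rhythm_range_hz = rhythm_range_hz,
                 rhythm_jitter_hz = rhythm_jitter_hz, mod_depth = mod_depth,
                 seed = seed),
            class = "synth_spec")
}

# Ornstein-Uhlenbeck background by exact discretisation
ou_noise <- function(n, dt, tau, sd) {
  a <- exp(-dt / tau)
  innov_sd <- sd * sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  innov <- rnorm(n - 1, 0, innov_sd)
  for (i in 2:n) x[i] <- a * x[i - 1] + innov[i - 1]
  x
}

# normalised difference-of-exponentials envelope on local time grid (s)
event_envelope <- function(tloc, rise, decay) {
  e <- exp(-tloc / decay) - exp(-tloc / rise)
  tpk <- rise * decay / (decay - rise) * log(decay / rise)
  e / (exp(-tpk / decay) - exp(-tpk / rise))
}

#' Generate a synthetic trace with ground truth
#'
#' Background = Ornstein-Uhlenbeck noise plus a slow sinusoidal drift (so
#' median detrending is non-trivially exercised).  Events occur at Poisson
#' times; each is a difference-of-exponentials excursion, optionally
#' multiplied by `1 + depth * sin(2 pi f t)` for rhythmic events.
#' Overlapping events are merged in the returned ground truth.
#'
#' @param spec A [synth_spec()].
#' @param channel Channel id of the returned trace.
#' @return List of class `"synth_trace"`: `trace` ([pe_trace()]) and `truth`
#'   (data frame `start`, `end`, `rhythmic`, `f_r`, `amplitude`, `merged`).
#' @examples
#' g <- generate_trace(synth_spec(duration_s = 20, seed = 42))
#' nrow(g$truth)
#' @export
generate_trace <- function(spec, channel = "ch1") {
  set.seed(spec$seed)
  gen <- generate_trace_impl(spec, channel)
  structure(gen, class = "synth_trace")
}

# internal: assumes RNG state is set by the caller
generate_trace_impl <- function(spec, channel = "ch1",
                                event_times = NULL, f_channel = NULL) {
  fs <- spec$sampling_hz
  n <- round(spec$duration_s * fs)
  t <- seq(0, by = 1 / fs, length.out = n)
  phase <- runif(1, 0, 2 * pi)
  x <- ou_noise(n, 1 / fs, spec$noise_tau_s, spec$noise_sd) +
    spec$drift_amp * sin(2 * pi * t / spec$drift_period_s + phase)

  if (is.null(event_times)) {
    n_ev <- rpois(1, spec$event_rate * spec$duration_s)
    event_times <- sort(runif(n_ev, 0, max(spec$duration_s - 1.5, 0)))
  }
  n_ev <- length(event_times)
  if (is.null(f_channel))
    f_channel <- runif(1, spec$rhythm_range_hz[1], spec$rhythm_range_hz[2])
  truth <- data.frame(start = numeric(0), end = numeric(0),
                      rhythmic = logical(0), f_r = numeric(0),
                      amplitude = numeric(0))
  for (ti in event_times) {
    amp <- runif(1, spec$amp_range[1], spec$amp_range[2])
    rhythmic <- runif(1) < spec$rhythm_fraction
    f_r <- if (!rhythmic) NA_real_
           else max(0.5, f_channel + rnorm(1, 0, spec$rhythm_jitter_hz))
    # an event must last long enough to carry its rhythm: slow-rhythm
    # events stretch so the envelope supports at least five cycles
    decay_ev <- spec$decay_s
    if (rhythmic) decay_ev <- max(decay_ev, 5 / (f_r * log(100)))
    # envelope support: out to where it has decayed to 1% of peak
    supp <- decay_ev * log(100)
    i0 <- round(ti * fs) + 1L
    i1 <- min(n, i0 + round(supp * fs))
    if (i0 >= n) next
    tloc <- (seq(i0, i1) - i0) / fs
    env <- amp * event_envelope(tloc, spec$rise_s, decay_ev)
    if (rhythmic)
      env <- env * (1 + spec$mod_depth * sin(2 * pi * f_r * tloc))
    x[i0:i1] <- x[i0:i1] + env
    truth <- rbind(truth, data.frame(start = ti, end = t[i1],
                                     rhythmic = rhythmic, f_r = f_r,
                                     amplitude = amp))
  }
  # merge overlapping ground-truth windows
  truth$merged <- logical(nrow(truth))
  if (nrow(truth) > 1L) {
    keep <- truth[1, , drop = FALSE]
    for (i in 2:nrow(truth)) {
      last <- nrow(keep)
      if (truth$start[i] <= keep$end[last]) {
        keep$end[last] <- max(keep$end[last], truth$end[i])
        keep$merged[last] <- TRUE
        keep$rhythmic[last] <- keep$rhythmic[last] || truth$rhythmic[i]
      } else {
        keep <- rbind(keep, truth[i, ])
      }
    }
    truth <- keep
    rownames(truth) <- NULL
  }
  list(trace = pe_trace(t, x, units = spec$units, channel = channel),
       truth = truth, spec = spec)
}

#' @export
print.synth_trace <- function(x, ...) {
  cat(sprintf("Synthetic %s trace: %.3g s at %g Hz, %d event(s), seed %d\n",
              attr(x$trace, "units"), x$spec$duration_s, x$spec$sampling_hz,
              nrow(x$truth), x$spec$seed))
  invisible(x)
}

#' Generate a simultaneously recorded channel pair
#'
#' Both channels carry the same event times (dual whole-cell recordings see
#' slice-wide events).  Rhythmic events oscillate at a common slice frequency
#' with independent per-channel jitter; background noise is independent.
#' Optionally the channels are rendered in different units.
#'
#' @param spec A [synth_spec()]; its `rhythm_fraction` applies to the pair.
#' @param shared_fraction Fraction of events shared between channels (1 =
#'   every event appears on both channels).
#' @param f_jitter_hz SD of the per-channel jitter around the slice rhythm
#'   frequency; `Inf` draws each channel's frequency independently.
#' @param mixed_units Render channel 2 in the other unit system.
#' @return List of class `"synth_pair"`: `ch1`, `ch2` (each a `synth_trace`
#'   list), `f_slice`.
#' @export
generate_pair <- function(spec, shared_fraction = 1, f_jitter_hz = 0.5,
                          mixed_units = FALSE) {
  stopifnot(shared_fraction >= 0, shared_fraction <= 1)
  set.seed(spec$seed)
  n_ev <- rpois(1, spec$event_rate * spec$duration_s)
  times <- sort(runif(n_ev, 0, max(spec$duration_s - 1.5, 0)))
  shared <- runif(n_ev) <= shared_fraction
  f_slice <- runif(1, spec$rhythm_range_hz[1], spec$rhythm_range_hz[2])
  indep <- is.infinite(f_jitter_hz)

  # rhythmicity is a slice property: either all events in the pair carry a
  # rhythm or none do (recording-site specific character)
  slice_rhythmic <- runif(1) < spec$rhythm_fraction
  spec$rhythm_fraction <- as.numeric(slice_rhythmic)

  spec2 <- spec
  if (mixed_units) {
    spec2$units <- if (spec$units == "nA") "mV" else "nA"
    scale <- if (spec2$units == "mV") 100 / 3 else 3 / 100
    spec2$amp_range <- spec$amp_range * scale
    spec2$noise_sd <- spec$noise_sd * scale
    spec2$drift_amp <- spec$drift_amp * scale
  }
  f_ch1 <- if (indep) NULL else f_slice + rnorm(1, 0, f_jitter_hz)
  f_ch2 <- if (indep) NULL else f_slice + rnorm(1, 0, f_jitter_hz)
  ch1 <- generate_trace_impl(spec, "cell1", event_times = times,
                             f_channel = f_ch1)
  ch2 <- generate_trace_impl(spec2, "cell2", event_times = times[shared],
                             f_channel = f_ch2)
  structure(list(ch1 = ch1, ch2 = ch2, f_slice = if (indep) NA else f_slice,
                 shared_times = times[shared]),
            class = "synth_pair")
}
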