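---
title: "Models of population events in balanced cortical networks with synaptic depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of population events in balanced cortical networks with synaptic depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popevent)
```

## The scientific problem

Spontaneously active cortical tissue spends most of its time in a low-rate,
asynchronous state in which recurrent inhibition tracks and cancels
recurrent excitation.  Sporadically, this state is interrupted by
*population events*: network-wide surges of activity lasting hundreds of
milliseconds, a subset of which carry a slow (2–12 Hz) internal rhythm.
`popevent` implements a family of models in which both regimes coexist:
excitation is balanced by fast recurrent inhibition, while **all excitatory
synapses undergo short-term depression**.  Depression of the E→I pathway
weakens inhibitory recruitment and thereby gates event *initiation*;
depression of the E→E pathway shapes the *rhythm* inside an event.

The package provides four interlocking layers:

1. a deterministic mean-field rate model with phenomenological depression
   (`simulate_meanfield()`),
2. sweep-based fixed-point / limit-cycle / bifurcation analysis of that
   model (`find_fixed_points()`, `find_limit_cycle()`,
   `sweep_saddle_node()`, `two_parameter_map()`),
3. a finite-size birth–death Markov process whose large-size limit is the
   rate model, simulated exactly by a hybrid Gillespie algorithm
   (`simulate_markov()`),
4. a leaky integrate-and-fire network with spike-recruited depression and
   facilitation (`simulate_spiking()`),

plus the intracellular-trace analysis pipeline (`detect_events()`,
`event_spectra()`, `classify_peak()`, `peak_pair_correlation()`) and a
synthetic-trace generator (`generate_trace()`, `generate_pair()`) that
provides ground truth for it.

## The mean-field model

The state is `(r_E, r_I, p_EE, p_IE)`: the active fractions of the
excitatory and inhibitory populations and the mean synaptic efficacies of
the two depressing pathways.  With the logistic transfer
`f(x) = 1/(1+exp(-x))`,

```
dr_E/dt       = -r_E + f( sqrt(N) (j_EE p_EE r_E - j_EI r_I + I_E) )
tau_I dr_I/dt = -r_I + f( sqrt(N) (j_IE p_IE r_E - j_II r_I + I_I) )
dp/dt         = (1 - p)/tau_r - a(r_E) p / tau_d        (per pathway)
a(r)          = m / (1 + exp(-beta (r - theta)))
```

All couplings are positive with the inhibitory terms carrying an explicit
minus sign.  Time is measured in units of the excitatory relaxation time;
`time_unit_ms = 10` converts to real time.  Default parameters
(`mf_params()`, `stp_params()`): `j_EE = 2, j_EI = 1, j_IE = 5, j_II = 2`,
`I_E = -0.12, I_I = -0.2`, `tau_I = 1`, `tau_r = 40`, `tau_d = 10`,
`m = 2`, `beta = 50`.  The two pathways share every plasticity constant
except the depression threshold, with `theta_EE > theta_IE` as the key
biological asymmetry: E→I synapses depress at lower presynaptic rates than
E→E synapses.

At frozen `r_E` the efficacy equation is linear with the globally
attracting equilibrium

```
p_hat(r_E) = (1/tau_r) / (1/tau_r + a(r_E)/tau_d),
```

which is ~1 for quiescent activity and ~0.11 at saturated activity with
`theta = 0.2` (the depressed state of the E→I pathway).  `plasticity_step()`
uses the exact exponential update, so composing steps over split intervals
is exact to machine precision.

### The size convention: connections vs. effective gain

The balanced scaling sets synaptic strengths to `j / sqrt(N)`, so the
transfer argument carries a gain `sqrt(N)`, where `N` is the network size
and `K = cN` the mean number of connections per neuron (`c` is the
connection density).  The package parameterises models by `K` and `c`
(`mf_params(K = 400, c = 0.4)` by default, giving gain `sqrt(1000)`).  The
distinction matters: the whole bifurcation skeleton — where the low state
is born, where the high state loses stability, the limit-cycle frequencies,
and the period-doubled windows — depends on the gain, not on the raw
connection count.  With the default `c = 0.4`, the canonical condition
"`K = 400`" places the within-event oscillation in the 4–8 Hz band,
produces a period-two cycle at `(theta_EE, theta_IE) = (0.5, 0.12)` and
makes `(0.5, 0.2)` excitable, which is the regime in which rare,
noise-triggered population events occur.

### Reduced models

Two reduced three-variable systems isolate the two roles of depression:

* **event initiation** (`mode = "fixed_pee"`, `p_EE = 1`): for low
  `theta_IE` only a high-activity state exists; a fold bifurcation in
  `theta_IE` creates a stable low state and a saddle.  The saddle is the
  threshold that finite-size fluctuations must cross to launch an event.
* **event rhythmicity** (`mode = "fixed_pie"`, `p_IE = 0.11`): for large
  `theta_EE` the high state is stable; lowering `theta_EE` destabilises it
  through a supercritical Andronov–Hopf bifurcation, and the resulting
  relaxation cycle between quiescence and saturation is the within-event
  rhythm, in the 4–8 Hz band over a wide threshold range.

### Numerical choices

* Integration: LSODA with `rtol = 1e-8`, `atol = 1e-10`; limit-cycle period
  estimates are tolerance-stable at these settings (halving the tolerances
  moves endpoint states by less than 1e-6).
* Fixed points: at equilibrium the efficacies and `r_I` are explicit
  functions of `r_E` (the `r_I` equation is strictly monotone and solved by
  Brent bracketing), so every equilibrium is a root of one scalar function
  of `r_E`.  Roots are bracketed on a 400-point grid and polished; this
  replaces multi-start Newton iteration, which proved unreliable near
  folds.  Stability comes from the finite-difference Jacobian in the active
  coordinates (tolerance 1e-8 on eigenvalue real parts).
* Folds: grid sweep of the fixed-point count, bisection of every interval
  where the count changes by two, to a bracket of 1e-4.
* Limit cycles: long integration (default 1500 time units), first half
  discarded, peaks of `r_E` clustered by amplitude (tolerance 1e-3) to
  recognise period-doubled orbits; the full period is the mean inter-peak
  interval times the number of distinct peak levels.  A trajectory whose
  late-time amplitude stays below 1e-5 counts as converged to a fixed
  point.  Period-doubling beyond period four is reported only as a peak
  count, not located precisely.
* The **event-scale qualifier** in `oscillation_band()`: near the
  supercritical Hopf point the cycle is a small, fast (~10–30 Hz) ringing
  around the high state, as for any supercritical Hopf.  A population-event
  rhythm must return to the quiescent state between surges, so a cycle
  qualifies only if its trough satisfies `r_E <= 0.1`.  Empirically the
  trough jumps from ~0.09 to ~0.20 across one grid step of `theta_EE`, so
  the classification is insensitive to the exact cutoff.
* Region labels in `two_parameter_map()`: a point with a single stable low
  state and no cycle is probed for excitability by bisecting the smallest
  instantaneous `r_E` bump that triggers a full excursion.  The point is
  *excitable* when this threshold is at most 0.075 — within reach of rare
  finite-size fluctuations at the default size (roughly seven standard
  deviations of the stationary count noise at `K = 400`) — and
  *monostable low* otherwise; excitable points are *rhythmic* when the
  triggered excursion carries repeated peaks.

## The finite-size birth–death model

Counts `n_E, n_I` jump by ±1 with birth rates
`N_E f(sqrt(N) (j_EE p_EE n_E/N_E - j_EI n_I/N_I + I_E))` (and the
analogous inhibitory rate divided by `tau_I`) and death rates `n_E` and
`n_I / tau_I`; births shut off at the population ceiling.  The efficacies
are piecewise-deterministic slow variables: propensities are frozen between
jumps, the waiting time is exponential in the summed propensity, and the
efficacies advance by their exact exponential update at the frozen `r_E`.
Initial efficacies sit at `p_hat(r_E(0))`.

The population sizes set the fluctuation scale `1/sqrt(N_E)` and default to
the connection count `K` while the transfer gain stays at `sqrt(N)`.  This
choice makes the low state metastable on laboratory timescales: at the
canonical thresholds `(0.5, 0.2)` events are rare threshold crossings of
the saddle with exponentially distributed waiting times (interval CV near
one), the event rate grows as the population shrinks, and the within-event
rhythm inherits the ghost of the deterministic cycle.  With both the sizes
and the gain at `N = 1000` the barrier is so high that no event occurs in
minutes of simulated time, which would contradict the rare-but-observable
phenomenology the model is meant to produce.

Population events in a rate trace are threshold upcrossings of `r_E = 0.5`
separated by at least 50 time units (0.5 s); within-event spectra resample
the trace at 0.1 time unit (1 ms), extract epochs from 0.2 s before the
upcrossing until activity has returned below `r_E = 0.1`, and average
unit-area Welch spectra across events.

## The spiking network

Leaky integrate-and-fire neurons (`N_E = 4000`, `N_I = 1000`) with
threshold-normalised voltages (threshold 1, reset 0), refractory period
2 ms, heterogeneous uniform resting potentials, independent white-noise
drive, Bernoulli connectivity and double-exponential synaptic kernels.
Synaptic amplitudes factor as `W * Jbar * D(t) * F(t)`; at each presynaptic
excitatory spike the depression factor multiplies by `d` and the
facilitation factor increments by `f` (per postsynaptic class), both
relaxing exponentially to 1 between spikes.  Inhibitory-presynaptic
synapses are static.  Integration is Euler–Maruyama at 0.1 ms with
`sqrt(dt)`-scaled Gaussian increments; the implementation realises each
kernel as a pair of exponential accumulators so that a spike of weight `w`
contributes exactly `w` time-integrated current.

The E→E pathway couples strong per-spike depression (`d = 0.24`) with
facilitation (`f = 0.85`), so at low rates the two factors cancel
(`five_pulse_ratio()` ≈ 1 at 15 Hz) while at high rates depression wins;
the E→I pathway lacks facilitation and depresses at all rates.  Raising
`f_IE` towards `f_EE` removes this asymmetry and, with it, the network's
ability to generate population events: an external 80 ms kick to the 200
highest-rate excitatory neurons (amplitudes `N(17.1/tau_E, 0.05)`) evokes a
rhythmic event at `f_IE = 0`, a brief arrhythmic response at intermediate
`f_IE`, and nothing at `f_IE = f_EE`.

The numeric profile shipped as `spiking_profile()` — membrane constants,
resting-potential ranges, noise intensities, connection probabilities,
baseline strengths, kernel and recovery timescales — is a package choice
calibrated once to place the network in the balanced asynchronous regime
at a ~1 Hz excitatory baseline with the kick-evoked event repertoire
described above.  The values are not measurements, and every one is
overridable.  Two structural constraints anchor the choice: resting
potentials must stay below threshold (otherwise a saturated state can
sustain itself after E→I depression silences inhibition and events never
terminate), and the product of inhibitory in-degree and I→E strength must
exceed the facilitation-compensated E→E drive at saturation (otherwise a
kick tips the network into permanent runaway).  Facilitation recovers
somewhat more slowly than depression (`tau_F = 200 ms` vs
`tau_D = 150 ms`), which preserves the low-rate cancellation of the E→E
pathway while letting depression dominate transients.

## The trace-analysis pipeline

* **Detrending**: subtract the centred 3 s running median re-anchored at
  the global mean.  The median is robust to brief event excursions, so
  events pass through nearly unchanged while drift is removed.
* **Two-pass detection**: first, contiguous deviations exceeding 5 mV
  (current clamp) or 0.15 nA (voltage clamp), padded by 200 ms before and
  500 ms after and merged when padding overlaps; second, automated
  refinement of each window — the event starts 200 ms before the initial
  upstroke (first crossing of 10% of the window's maximum smoothed slope)
  and ends at the last point before the slope stays within 5% of that
  maximum for at least one second.  Windows without a qualifying flat tail
  keep their first-pass end and are flagged.
* **Denoising**: first-order Savitzky–Golay smoothing over ~10 ms
  (rescaled to the sampling rate), a centred moving average that attenuates
  power above ~100 Hz.
* **Spectra**: per event — denoise, remove mean and linear trend, Welch
  periodogram (Hann window, 50% overlap, segment length capped at 2 s,
  four-fold zero padding), unit-area normalisation; per recording —
  average across events, normalise to maximum one.  Non-event spectra use
  every non-event period longer than 100 ms.  Events shorter than 0.25 s
  are skipped with a warning.
* **Peak classification** (`classify_peak()`): event spectra always carry
  broad low-frequency power from the event envelope itself, so the maximum
  of the spectrum falling inside the 1–20 Hz band does not by itself
  indicate a rhythm.  A qualifying peak must be an interior local maximum
  separated from lower frequencies by an interior spectral valley at least
  20% of the peak height deep, with peak height at least 10% of the
  spectrum maximum, after 1 Hz moving-average smoothing; spectra whose
  in-band mean power does not exceed twice the mean power in the octave
  above the band are classified as flat (noise-like) up front.  The
  valley requirement rejects monotone envelope lobes; the flatness gate
  rejects white-noise spectra whose wiggles would otherwise pass any local
  criterion.  For non-peaked spectra the full width at half maximum of the
  low-frequency lobe is reported instead.
* **Paired recordings**: with no natural assignment of "cell 1"/"cell 2"
  within a simultaneously recorded pair, `peak_pair_correlation()` computes
  the Pearson correlation of peak frequencies under 10,000 random
  within-pair label assignments and reports the distribution with its mean
  and median (both, since neither is canonically preferable).

## The synthetic-trace generator

`generate_trace()` emulates the statistical structure of the
never-deposited slice recordings: an Ornstein–Uhlenbeck background
(exactly discretised; SD 0.03 nA, 100 ms correlation time) plus a slow
sinusoidal drift (0.05 nA, 20 s) so that median detrending is
non-trivially exercised; events at Poisson times (0.2/s) with
difference-of-exponentials envelopes (50 ms rise, 200 ms decay — several
hundred ms excursions echoing the synaptic-kernel shape) and uniform
amplitudes 0.15–0.5 nA (5–20 mV in current-clamp units); rhythmic events
stretch so their envelope supports at least five rhythm cycles (a 2 Hz
rhythm cannot live inside a 500 ms excursion); a fraction
(default one third) of *recordings* is rhythmic — rhythmicity and the
rhythm frequency are recording-site properties, drawn once per trace from
2–12 Hz and shared by all events with a small per-event wobble (0.2 Hz),
matching the slice-level clustering of rhythmicity in the data this
emulates.  `generate_pair()` shares event times and the slice frequency
across two channels with independent noise and per-channel jitter,
optionally in different unit systems.

What the generator does **not** emulate: biophysical membrane dynamics,
measurement artefacts, electrode drift steps, truncated events at
recording boundaries, or any dependence of event shape on the recording
site.  Tests that pass on these surrogates therefore validate the
*pipeline logic* (detection geometry, spectral normalisation, label
shuffling), not performance on real tissue.

Known limitation: rhythms at the very bottom of the 2–12 Hz range
(roughly below 3 Hz) remain spectrally close to the event envelope lobe
even in stretched events, and the classifier misses a fraction of them at
modulation depth 0.5.  This is a time-frequency limit of short recordings
rather than a property of the criterion.

## Problem sizes used in tests

The test suite runs the tiny-network master-equation cross-check at
`N_E = N_I = 3` against a directly solved 16-state stationary
distribution; ensemble-mean convergence at size 10⁴ over 200 seeds on a
short horizon; rare-event statistics over (2–4)×10⁴ time units at sizes
200–400; detection metrics over ~200 synthetic events; and the spiking
checks at the full `N_E = 4000, N_I = 1000` with multi-second horizons.
These sizes were chosen so each property is measured with comfortable
statistical margin while the whole suite stays desk-scale.
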