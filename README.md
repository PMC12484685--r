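# popevent

Models and analysis tools for **population events in balanced cortical
networks with short-term synaptic depression**.

Spontaneously active cortical tissue sits in a low-rate asynchronous state
in which recurrent inhibition tracks and cancels recurrent excitation, yet
that state is sporadically interrupted by network-wide surges of activity —
*population events* — lasting hundreds of milliseconds, some of which carry
a slow (2–12 Hz) internal rhythm.  `popevent` implements a model family in
which both regimes coexist because all excitatory synapses depress:
depression of E→I synapses (threshold θ_IE) gates event *initiation*,
depression of E→E synapses (threshold θ_EE > θ_IE) shapes event
*rhythmicity*.

## The model

The core is a two-population rate model with phenomenological depression.
With the logistic transfer f(x) = 1/(1+e^(−x)),

    dr_E/dt       = −r_E + f( √N ( j_EE p_EE r_E − j_EI r_I + I_E ) )
    τ_I dr_I/dt   = −r_I + f( √N ( j_IE p_IE r_E − j_II r_I + I_I ) )
    dp_αE/dt      = (1 − p_αE)/τ_r − a_α(r_E) p_αE / τ_d
    a_α(r)        = m / (1 + e^(−β (r − θ_αE)))

where N = K/c is the network size behind the balanced 1/√N synaptic
scaling (K connections per neuron at density c).  Around this live:

* **bifurcation sweeps** — fixed points, stability, folds, limit cycles and
  a two-parameter (θ_EE, θ_IE) regime map;
* a **finite-size birth–death Markov process** with the same skeleton,
  simulated exactly by a hybrid Gillespie algorithm (counts jump, the
  efficacies evolve piecewise-deterministically between jumps) — this is
  where rare, noise-triggered events with exponential waiting times arise;
* a **leaky integrate-and-fire network** (4000 E + 1000 I neurons) with
  spike-recruited depression (D → D·d) and facilitation (F → F+f), where
  facilitation of the E→E pathway implements the threshold asymmetry
  biologically and an external "kick" probes the event repertoire;
* the **intracellular-trace pipeline** — median detrending, two-pass event
  detection, Savitzky–Golay denoising, Welch within-event spectra,
  rhythmicity classification, and label-shuffled peak correlation for
  paired recordings — fed by a **synthetic-trace generator** with known
  ground truth.

## Worked example

Simulate the finite-size network in the excitable regime, detect the rare
population events and measure their internal rhythm:

```r
library(popevent)

mp    <- mf_params()                 # K = 400 connections, gain sqrt(1000)
pp_ee <- stp_params(theta = 0.5)     # E-to-E depression threshold
pp_ie <- stp_params(theta = 0.2)     # E-to-I threshold (lower: initiates)

sim <- simulate_markov(mp, pp_ee, pp_ie, T = 3e5, seed = 7)
detect_population_events_rate(sim)
#> 34 population events in 3e+05 time units (rate 0.000113 per unit)
#>   inter-event interval CV: 1.04

markov_event_spectra(sim)
#> Averaged spectrum over 34 event(s); peak at 7.59 Hz
```

Three thousand seconds of network time contain 34 events; their waiting
times are exponential-like (CV ≈ 1, the signature of a rare threshold
crossing), and the averaged within-event spectrum peaks near 8 Hz — the
ghost of the deterministic limit cycle that lives nearby in parameter
space.  The deterministic counterpart:

```r
find_limit_cycle(mp, pp_ee, pp_ie, mode = "fixed_pie")
#> Limit cycle: period 20.131 units (4.97 Hz), 1 distinct peak level(s)
#>   r_e in [0.048, 0.985]
```

The same machinery reproduces the depressed-state efficacy in closed form:

```r
plasticity_fixed_point(1, pp_ie)
#> [1] 0.1111111
```

For recordings (or surrogates), the analysis pipeline runs end to end:

```r
g   <- generate_trace(synth_spec(duration_s = 40, event_rate = 0.25,
                                 rhythm_fraction = 1,
                                 rhythm_range_hz = c(6, 6), seed = 5))
res <- detect_events(g$trace)
res$spectrum
#> Averaged spectrum over 11 event(s); peak at 6.06 Hz
```

A command-line interface wrapping these functions ships in
`inst/cli/popevent` (subcommands `simulate-meanfield`, `bifurcation-sweep`,
`simulate-markov`, `simulate-spiking`, `synth`, `detect-events`,
`spectra`).

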