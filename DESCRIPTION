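Package: popevent
Title: Population Events in Balanced Cortical Networks with Short-Term
    Synaptic Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analysis tools for interleaved asynchronous and
    population-event dynamics in balanced excitatory-inhibitory cortical
    networks whose excitatory synapses undergo short-term depression.
    Provides a deterministic mean-field rate model with phenomenological
    depression, sweep-based fixed-point, limit-cycle and bifurcation
    mapping, a finite-size birth-death Markov simulator (hybrid Gillespie
    with piecewise-deterministic plasticity), a leaky integrate-and-fire
    network with spike-recruited depression and facilitation, an
    intracellular-trace event-detection and Welch spectral pipeline, and a
    synthetic-trace generator that provides ground truth for the analysis
    pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
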