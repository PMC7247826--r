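Package: ucnsim
Title: Hybrid Simulation of an Ultra-Compact Thyristor-Based Spiking Neuron
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the ultra-compact neuron (UCN), a leaky
    integrate-and-fire circuit whose firing element is a hysteretic
    threshold-switching thyristor (SCR). Circuit variants (base block,
    differentiator input, gate feedback, inhibitory topology) are compiled
    to hybrid dynamical systems with continuous membrane states and a
    discrete device state, integrated with accurate switching-event
    localization. Includes stimulus waveform generators, spike-train
    analytics (interspike intervals, bursts, adaptation index, f-I curves,
    excitability classes), a predicate-based classifier for the canonical
    biologically relevant spiking behaviors, and a scenario battery that
    reproduces twelve of them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
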