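Package: spikewm
Title: Spiking Working-Memory Circuits with Spike-Timing-Dependent Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a small prefrontal working-memory circuit of Izhikevich
    spiking neurons in which a stimulus is encoded as a rank-order spike
    pattern on a subset of coding neurons, stored by nearest-neighbor
    spike-timing-dependent plasticity acting on multi-delay excitatory
    synapses with short-term depression and facilitation, and recalled under
    a delay-match-to-sample protocol in either a persistent-activity or an
    activity-silent regime. Includes polychronization-based pattern
    detectors, trial and session orchestration, sliding-window firing-rate
    binning, SVM population decoding, weight-distribution summaries, and a
    command-line interface with deterministic run archives.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
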