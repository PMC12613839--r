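Package: meacircuit
Title: Analysis of Single-Neuron Microcircuit Recordings on Multielectrode Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing extracellular recordings of few-neuron
    microcircuits grown in microchannel scaffolds on multielectrode arrays
    (MEAs): high-pass filtering and common median referencing, MAD-threshold
    spike detection, action-potential conduction-velocity estimation from
    baseline-SD threshold crossings along known electrode geometry,
    interspike-interval histogram comparison by Kullback-Leibler divergence,
    spike-contrast synchrony, participation ratio, MaxInterval burst and
    network-burst detection, and evoked-response latency analysis for optical
    and electrical stimulation. Includes a synthetic MEA recording simulator
    with per-spike ground truth (assigned conduction velocities, burst
    synchrony, stimulus responses) for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
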