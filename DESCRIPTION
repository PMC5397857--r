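Package: netphase
Title: Network Structure, Oscillator Phase, and Directionality in Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying how the structure of a coupled-oscillator
    network shapes the phase dynamics and directionality of its nodes. The
    package integrates Kuramoto-type phase oscillators with phase
    offset (frustration) or explicit transmission delays on arbitrary weighted
    networks, and predicts each node's stationary relative phase from network
    structure alone via two analytic solvers: a mean-field approximation (MFA)
    and a local order parameter (LOP) fixed point. Phase-based directionality
    is quantified with the directed phase lag index (dPLI) and its absolute
    value, the phase lag index (PLI). A signal-analysis pipeline (band
    selection at the spectral peak, zero-phase Butterworth filtering, Hilbert
    phases, epoching, PLI-weighted functional networks, thresholded degree)
    applies the same measures to multichannel oscillatory recordings, with a
    synthetic-signal generator for testing. Hubs (high-degree nodes) are
    predicted and observed to phase-lag and act as directional targets;
    peripheral nodes phase-lead and act as sources.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
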