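Package: sisrmux
Title: Self-Induced Stochastic Resonance in Delayed Multiplex FitzHugh-Nagumo Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of self-induced stochastic resonance (SISR)
    in two-layer multiplex networks of FitzHugh-Nagumo neurons with time-delayed
    electrical (gap-junction) and sigmoidal chemical synapses. Provides a fast
    stochastic delay integrator (Rcpp), spike detection and interspike-interval
    coefficient-of-variation statistics, the double-well energy-landscape theory
    that predicts the admissible noise window for SISR, renewal-process fixtures
    for validating the statistics, and pipeline helpers for noise sweeps and
    multiplexing-parameter heatmaps.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
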