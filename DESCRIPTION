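Package: homeostat
Title: Design and Analysis of Synthetic Gene Circuits for Artificial Tissue Homeostasis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic multicellular simulators for a family of
    synthetic gene-circuit designs that maintain an artificial tissue homeostasis:
    population-control feedback, toggle-switch commitment, an asynchronous
    oscillator, and a lateral-inhibition commitment throttle. Includes a spatial
    chemical-Langevin engine on a 2-D lattice with diffusing quorum signals, an
    exact next-reaction stochastic simulator for the detailed reaction network,
    a signal-to-noise homeostasis metric with spatial and phase statistics,
    random-sampling high dimensional model representation (RS-HDMR) global
    sensitivity analysis, genetic-algorithm optimization of the population-control
    module with an anti-hysteresis objective, clustered parameter-sensitivity
    signatures, phenotypic sensitivity analysis of the heterogeneity modules, and
    constrained Bayesian-network structure inference linking rate constants,
    module phenotypes, and system performance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
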