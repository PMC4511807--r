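Package: galswitch
Title: Timing and Variability of GAL Network Induction Under Glucose Depletion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying how the rate of extracellular glucose depletion
    shapes the timing and cell-to-cell variability of galactose (GAL) network
    induction in budding yeast. Implements a threshold model of induction
    timing with least-squares fitting and bootstrap uncertainty, a delayed
    stochastic simulation (dSSA) of a minimal Gal4p/Gal2p model with
    carbon-source-dependent energy scaling, time-varying glucose input,
    energy-scaled growth and volume-triggered division with binomial protein
    partitioning, feature extraction from single-cell fluorescence
    trajectories (initiation points, accumulation times, cell-cycle
    classification into glucose/diauxie/galactose regimes), and a
    synthetic-data generator so every analysis stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
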