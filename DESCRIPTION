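Package: mirffl
Title: Noise Buffering by MicroRNA Feed-Forward Loops in Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how microRNA incoherent feed-forward loops
    shape the mean and cell-to-cell variability of target protein expression.
    Provides an exact stochastic simulation (Gillespie) engine for small
    reaction networks with mass-action and Hill-modulated propensities,
    builders for two microRNA feed-forward circuit variants (translational
    repression and microRNA-directed mRNA degradation) with a CD69-calibrated
    instance, copy-number estimation arithmetic, generators of synthetic
    flow-cytometry event tables with known ground truth, noise statistics for
    cytometry data (coefficient of variation, ratio-based technical-noise
    bounds, mixture analytics, computational unmixing), and orthogonal-
    regression quantification of dual-fluorescence reporters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    deSolve,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
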