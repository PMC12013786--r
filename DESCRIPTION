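Package: muflex
Title: Motor Unit Manifolds, Recruitment Flexibility and Spiking Pool Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing populations of concurrently active motor units
    decomposed from high-density surface electromyography. Provides spike-train
    containers and preprocessing (Hanning-kernel rate smoothing, continuity
    filtering, detrending, duplicate resolution, recruitment thresholds),
    maximum-likelihood factor analysis of smoothed firing rates with a
    surrogate-slope criterion for latent dimensionality, displacement and
    dispersion statistics quantifying deviation from a one-dimensional
    recruitment manifold, motor-unit action-potential geometry on electrode
    grids, and a conductance-based leaky integrate-and-fire motor-neuron pool
    simulator with optional Renshaw-cell recurrent inhibition. Seeded synthetic
    generators with known ground truth make every analysis stage testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
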