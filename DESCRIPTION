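Package: qmdmd
Title: Iterative Hybrid Quantum/Discrete Molecular Dynamics Sampling for
    Metal-Dependent Active Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An iterative multiscale sampling-and-mechanism pipeline for
    metal-dependent enzyme active sites, modelled on the alternating
    quantum-cluster / discrete molecular dynamics (DMD) protocol used to study
    catechol-O-methyltransferase. Provides three-domain partitioning with a
    breathing boundary, hydrogen-capped active-site cluster extraction,
    constrained event-driven DMD with stepwise potentials and an Andersen
    thermostat, Kabsch-RMSD trajectory clustering with centroid and
    lowest-energy representatives, a rank-sum scoring and energy-based
    iteration acceptance rule, a pluggable analytic active-site energy backend
    with partial optimization and finite-difference Hessians, stationary-point
    (reactant/transition-state/product) analysis of an SN2 methyl-transfer
    step with zero-point-corrected ensemble-averaged barriers, and named
    active-site geometry observables with ensemble statistics. Ships a
    synthetic toy metal-site generator with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
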