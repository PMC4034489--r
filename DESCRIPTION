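Package: glioscale
Title: Cross-Scale Glioblastoma Growth Simulation and Multiscale Sensitivity
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hybrid multiscale model of glioblastoma growth that couples a
    lattice agent-based cellular layer, an explicit reaction-diffusion glucose
    field with occupancy-dependent diffusivity, and a per-cell nine-species
    miR-451/AMPK/mTORC1 signalling network deciding between migrating,
    proliferating and quiescent phenotypes (the Go-or-Grow dichotomy).
    Includes the multiscale local sensitivity analysis pipeline that perturbs
    molecular reaction parameters one at a time, measures cellular-scale
    endpoints (steps to boundary, final total/migrating/proliferating cell
    counts), computes normalised sensitivity coefficients, and screens
    combined two-parameter perturbations for joint slow-down of tumour
    expansion and shrinkage of tumour volume. A fast log-linear surrogate
    endpoint generator makes every pipeline stage testable without running
    the full simulator.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
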