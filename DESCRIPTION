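Package: tdlusim
Title: Agent-Based Simulation of Immune Cell Infiltration in Breast Lobular Epithelium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stochastic lattice agent-based model of epithelial and immune cell
    interactions in cross-sections of terminal duct lobular units (TDLUs) of the
    human breast over menstrual cycles. Epithelial turnover follows
    hormone-modulated proliferation and apoptosis rates; damaged and dying
    epithelial cells secrete chemokines (modelled as reaction-diffusion fields)
    that activate, attract and recruit effector and regulatory immune cells.
    Includes trafficking calibration against per-phase relative immune cell
    numbers, spatial statistics for infiltrate organisation (radial distribution
    function with power-law fits, contact profiles, cluster detection),
    replicate experiment orchestration with parameter sweeps, and a
    three-regime inflammation classifier.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    igraph,
    mgcv,
    signal
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
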