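Package: aggsim
Title: Agent-Based Simulation of Molecular Aggregation at the Plasma Membrane
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Density-coupled Brownian agents on a toroidal two-dimensional
    membrane patch. Implements the localized linearised Ripley's L statistic
    with a cell-list accelerator and brute-force oracle, displacement-versus-
    density motion rules ("desire for clustering") with linear, floored, tent
    and quadratic profile families, reflective actin-mesh barriers, a compiled
    simulation core with seeded replicate ensembles, density-based cluster
    descriptors for the resulting point patterns, and convergence, regime and
    cut-off analytics over clustering-target sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
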