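Package: fetalfold
Title: Fetal Brain Phantom Morphometry and Cohort Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates labeled fetal-brain phantoms with controllable cortical
    folding, computes tissue volumetry from label volumes, extracts the
    gray-white junction surface and per-hemisphere convex hulls, measures
    cortical folding (surface area, local gyrification index, sulcal depth),
    and runs the full cohort-comparison statistical battery: generalized
    estimating equations for repeated fetal scans with robust covariance and
    least-squares means, maternal-distress stratification, and
    Benjamini-Hochberg false discovery rate control within outcome families.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    yaml,
    digest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
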