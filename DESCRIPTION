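Package: tissuemap
Title: Neighborhood-Based Spatial Analysis of Multiplexed Tissue Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts annotated cell tables from multiplexed 2D/3D tissue
    imaging into local neighborhoods, machine-learned tissue regions, and
    quantitative spatial statistics. Cells are binned into raster-scanned or
    object-centered cylindrical/spherical neighborhoods; neighborhoods are
    clustered into tissue regions with a one-dimensional self-organizing map,
    with the region count selected by the Davies-Bouldin criterion; downstream
    tools compute pairwise spatial correlations of cell types, pseudo-space
    orderings, alpha-shape region surfaces with signed distances, nearest-object
    distances with random-point controls, and region-adjacency network maps.
    A seedable synthetic-tissue generator provides compartmentalized point
    patterns with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    purrr,
    RANN,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    Rtsne,
    testthat (>= 3.0.0),
    uwot
Config/testthat/edition: 3
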