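Package: hexclust
Title: Adjacency-Constrained Clustering of Hexagonally Binned Cytometry Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated gating of mass-cytometry (CyTOF) data by
    adjacency-constrained, marker-weighted complete-linkage clustering of
    hexagonally binned two-dimensional embeddings (t-SNE), together with
    downstream cohort statistics: per-sample cluster occupancy, stratified
    Mann-Whitney testing with Benjamini-Hochberg correction, PCA plus type-II
    MANOVA variance partitioning over clinical covariates, and a
    permutation-based screen for associations between stimulated functional
    marker frequencies and a height-for-age (HAZ) covariate. Includes a
    synthetic-cohort generator with known ground truth, a staged pipeline
    driver with run manifests, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Rtsne,
    car,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ape,
    cluster,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
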