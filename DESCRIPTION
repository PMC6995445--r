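Package: fcgeodesic
Title: Geodesic Distance and Participant Fingerprinting for Functional
    Connectivity Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometry-aware comparison of functional connectivity (FC)
    matrices. Correlation matrices live on the cone of symmetric
    positive-semidefinite matrices, and the affine-invariant geodesic
    distance respects that geometry where Pearson dissimilarity of the
    vectorized matrices does not. The package builds FC matrices from
    ROI time series, computes geodesic and Pearson (dis)similarities with
    identity-perturbation regularization for rank-deficient inputs, and
    implements the participant-identification ("fingerprinting")
    framework built on them: symmetric 1-nearest-neighbour
    identification, two-level bootstrap inference on accuracy
    differences with Fisher-z t-tests, segment-length and subnetwork
    experiments, cross-condition transfer tables, and non-metric
    multidimensional scaling for visualization. A multivariate-normal
    factor-model generator produces multi-participant, multi-condition
    synthetic studies so every experiment can be exercised without
    access-restricted neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
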