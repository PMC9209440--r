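Package: symphage
Title: Automated Age-at-Death Estimation from 3D Pubic Symphyseal Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates adult age-at-death from triangulated 3D scans of the
    pubic symphyseal articular surface. Six quantitative surface features are
    extracted from each scan (standard deviation of local Dirichlet normal
    energy, standard deviation of local mean curvature, counts of detected,
    horizontally and vertically oriented elliptical bulge regions, and the
    number of holes in the scan) and combined by multi-linear regression.
    Includes STL/PLY mesh input/output, pose canonicalization, height-grid
    rasterization, bulge segmentation with moment-ellipse fitting, ordinary
    least squares fitting with greedy AIC feature selection, baseline
    estimators, error metrics with fivefold cross-validation, and a synthetic
    generator of age-graded symphyseal-like surfaces for ground-truth testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    png,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
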