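Package: fvcmap
Title: Fractional Vegetation Cover from UAV RGB Orthomosaics and Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Object-based estimation of fractional vegetation cover (FVC) from
    high-resolution RGB orthomosaics and RGB-attributed dense point clouds, as
    used to monitor ecological restoration of mine tailings impoundments.
    Provides nine visible-band vegetation indices with index-selection
    diagnostics (per-class error statistics, gray-histogram bimodality),
    multi-resolution region-merging segmentation under a weighted color/shape
    homogeneity criterion with local-variance (LV-ROC) optimal-scale
    estimation, a bagged CART random-forest classifier of image objects with
    full confusion-matrix accuracy evaluation (producer's/user's accuracy,
    overall accuracy, kappa), and transfer of classified 2D vegetation objects
    onto 3D point clouds with mapping-error and FVC reporting. A synthetic
    tailings-scene generator (raster, terrain, point cloud, truth mask) makes
    the whole pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    randomForest,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
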