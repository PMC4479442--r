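Package: canopyOBIA
Title: Object-Based Delineation and 3-D Canopy Metrics of Tree Plantations
    from UAV Orthomosaics and Surface Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automatic delineation of individual trees and tree-rows from
    co-registered UAV orthomosaic and digital surface model (DSM) rasters
    using object-based image analysis: multiresolution region-merging
    segmentation, Otsu thresholding of vegetation indices (ExG or NDVI),
    canopy height above a locally selected bare-soil baseline, hierarchical
    merging of tree objects into entities, and per-entity position, canopy
    axes, projected area, height and pixel-integrated crown volume. Includes
    validation statistics (overall classification accuracy, average feature
    error, regression fit, ellipsoid crown volume) and a synthetic-orchard
    generator with analytic ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'sceneIO.R'
    'spectral.R'
    'segmentation.R'
    'classify.R'
    'features.R'
    'validation.R'
    'synthetic.R'
    'pipeline.R'
    'cli.R'
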