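Package: fidreg
Title: Fiducial-Based Rigid Registration of Multi-Temporal 3D Surface Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Registration of three-dimensional surface scans of the same
    object acquired at different time points, using a cubic registration
    block as a localized fiducial. Provides rigid-transform algebra and
    closed-form (Kabsch) superposition, iterative-closest-point alignment
    computed on extracted planar block features and propagated to the whole
    model, simulation of structured-light surface scans of a parametric
    bone-plateau phantom carrying the block, quantification of registration
    error as unsigned surface variation over a region of interest, and a
    factorial experiment driver that studies how fiducial size (as a
    percentage of the scanner field of view) and the number of selected
    orthogonal planes control whole-object registration error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    Rcpp,
    jsonlite,
    mgcv
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'deviation.R'
    'experiment.R'
    'features.R'
    'fidreg-package.R'
    'geometry.R'
    'io.R'
    'registration.R'
    'synthetic.R'
    'transforms.R'
    'utils.R'
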