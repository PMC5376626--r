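Package: rootbench
Title: Synthetic Ground-Truth Benchmarking for Root Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates libraries of simulated two-dimensional root systems
    (fibrous and tap-rooted) with exact ground-truth morphology, serializes
    them as Root System Markup Language (RSML), rasterizes them to images at
    a known physical resolution, degrades the images with salt-and-pepper
    noise, and re-measures them with a skeleton- and shape-based descriptor
    extractor. Paired ground-truth/descriptor tables feed an evaluation
    layer (mean relative error, r-squared matrices, overlap-index binning,
    PCA, MANOVA) and a random-forest calibration framework that learns to
    recover ground-truth traits from image descriptors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tools,
    xml2,
    jsonlite,
    png,
    withr,
    randomForest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
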