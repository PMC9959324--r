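Package: hsicnn
Title: Hyperspectral Histopathology Classification with 3D Convolutional
    Networks and Focal Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying hematoxylin-and-eosin stained liver
    tissue from visible/near-infrared hyperspectral microscopy cubes.
    Provides ENVI cube input/output with white/dark radiometric
    calibration, patch tiling with blank-area filtering, alternative
    spectral representations (constant-stride band sampling, incremental
    principal components, Gaussian-synthesized RGB), a compact four-block
    3D (and 2D) convolutional network trained with a class-balanced focal
    loss, imbalance-aware evaluation centred on the Matthews correlation
    coefficient, and a synthetic tissue-phantom generator so the whole
    pipeline can be exercised end to end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
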