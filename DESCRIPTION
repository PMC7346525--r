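Package: rcseg
Title: Registration-Classification Segmentation of Multimodal Plant Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-step registration-classification segmentation (RCS) of
    greenhouse plant shoots from paired fluorescence (FLU) and visible-light
    (VIS) images. High-contrast FLU images are pre-segmented by color-distance
    clustering against an empty-background reference, co-registered to the VIS
    frame by similarity-transform optimisation of mask overlap, and the
    transferred mask is refined by an ensemble of eight binary classifiers
    acting on average colors of k-means regions (AC-KMR) in a 10-dimensional
    HSV+Lab+CMYK color space with Eigen-color (PCA) projection. Residual small
    artefacts are removed by a feature-based classifier vote. Includes a
    synthetic multimodal fixture generator with ground truth, a case-scenario
    training/evaluation grid, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    MASS,
    e1071,
    kernlab,
    nnet,
    jsonlite,
    png,
    tiff,
    stats,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    farver,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
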