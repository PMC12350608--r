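Package: otoshape
Title: Otolith Contour Shape Analysis via Stationary Wavelet Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Morphometric analysis of fish otolith outlines for population
    discrimination. Closed otolith silhouettes are resampled to a 512-point
    centroid-distance signature, decomposed with the undecimated a trous
    wavelet transform (B3-spline kernel), and summarised in a covariance-PCA
    morphospace with broken-stick component retention and allometric size
    correction.  Population structure is tested with PERMANOVA on Manhattan
    distances, classified with a SMOTE-balanced single-hidden-layer
    perceptron under leave-one-out cross-validation, and summarised into
    morphotypes by Ward hierarchical clustering.  A synthetic otolith-shape
    generator provides reproducible test beds with planted population
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    tools,
    mgcv,
    nnet,
    cluster,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    mclust,
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
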