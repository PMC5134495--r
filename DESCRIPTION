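Package: lenslessSR
Title: Single-Frame Super-Resolution for Lensless Cell Imaging and Counting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machine-learning single-frame super-resolution for lensless
    (shadow) images of blood and tumour cells, together with the surrounding
    detection, recognition and counting pipeline of a microfluidic lensless
    cytometer. Two engines are provided: an extreme-learning-machine
    regressor that learns high-frequency residuals with closed-form ridge
    output weights (ELMSR), and a three-layer convolutional network trained
    by momentum stochastic gradient descent (CNNSR). The package also
    implements Catmull-Rom bicubic resampling, the mean structural
    similarity (MSSIM) metric and strongest-MSSIM cell-type classification,
    temporal-difference cell detection and increment counting over frame
    sequences, and a synthetic phantom generator that emulates per-type cell
    morphology and the contrast loss, blur, pixelation and noise of lensless
    shadow imaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    yaml,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
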