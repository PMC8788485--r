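Package: medreg
Title: Penalized-Likelihood PET Reconstruction with Similarity-Driven
    Median Regularization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-dimensional emission-tomography image
    reconstruction by penalized likelihood with a weighted median
    regularizer whose weights are driven by non-local-means style patch
    similarities (SDMR). Includes a parallel-beam strip-integral
    projector and sinogram simulator, complete-data ordered-subsets EM
    (COSEM) likelihood updates, an alternating optimization-transfer
    scheme for the image and its auxiliary median image,
    super-resolution reconstruction on a finer pixel grid from a single
    low-resolution sinogram, comparator regularizers (non-weighted
    median, local quadratic, local non-quadratic, non-local quadratic),
    parametric circle and brain phantoms with region-of-interest masks,
    and an evaluation suite (mean percentage error, contrast recovery,
    SSIM, PSNR, RMSE, MAE, VIF, line profiles, background-noise based
    smoothing-parameter matching).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
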