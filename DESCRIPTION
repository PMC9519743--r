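Package: biraster
Title: Correction of Bidirectional Raster-Scan Misalignment in Photoacoustic Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for doubling the effective B-scan rate of raster-scanned
    optical-resolution photoacoustic microscopy (OR-PAM) by correcting the
    nonlinear misalignment between forward and backward sweeps of a
    bidirectional fast-axis scan. Includes a synthetic vascular phantom and
    galvanometer acquisition simulator producing paired bidirectional /
    unidirectional images, a multiscale fully-dense U-Net generator with
    pixel-shuffle upsampling trained adversarially against a five-layer
    convolutional discriminator under a composite adversarial + MAE + SSIM
    loss, a full-reference image quality suite (SSIM, MS-SSIM, PSNR, MAE,
    MSE and the blur absolute difference, BAD), classical filter baselines,
    slice-wise correction of 3D amplitude volumes with depth-encoded
    rendering, and a reproducible simulate/train/evaluate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage,
    stats,
    tools,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
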