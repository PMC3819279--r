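Package: tedi
Title: True Edge-Directed Interpolation for Grayscale Medical Images
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-image upscaling that preserves edge structure, aimed at
    low-resolution grayscale medical images such as fetal spine MRI. A bilinear
    pre-interpolation is refined by sharpening "true" edges (detected in the
    low-resolution input by a Canny detector, classified into four orientation
    bins and projected onto the high-resolution grid) and softening "pseudo"
    edges (detected only in the pre-interpolated image). Includes the
    covariance-based NEDI interpolator and a Canny-edge modification (CEM)
    baseline, full-reference quality metrics (SNR, PSNR, SSIM, mutual
    information), a seeded phantom generator that stands in for confidential
    clinical images, and a degrade-then-interpolate benchmark harness with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
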