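Package: nvca
Title: Noise Variance Conditioned Average Filtering for Low-Dose Fluoroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Spatio-temporal denoising of low-dose X-ray fluoroscopy
    sequences with the Noise Variance Conditioned Average (NVCA) filter,
    an edge-preserving conditioned mean over an N x N x K causal
    neighborhood whose inclusion threshold tracks the local quantum-noise
    standard deviation. Includes the mixed Poissonian-Gaussian noise
    model with its affine expected value-variance law, temporal
    estimation of the noise parameters from motionless sequences,
    spatial and temporal autocovariance diagnostics, the generalized
    Anscombe variance-stabilizing transform and its algebraic inverse,
    synthetic step and moving-insert phantoms with ground truth, and
    image-quality metrics: line-spread-function FWHM from error-function
    edge fits, contrast-to-noise ratio, and the FSIM feature-similarity
    index. Frame sequences are read and written as multi-frame TIFF or
    raw binary with JSON sidecars, and a small command-line interface
    ties simulation, estimation, denoising and evaluation together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
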