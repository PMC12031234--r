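Package: lsraman
Title: Computational Enhancement for Multi-Modal Light-Sheet Raman Microscopy
Version: 0.1.0
Authors@R:
    person("CeMOS", "Imaging", email = "imaging@example.org", role = c("aut", "cre"))
Description: Unsupervised denoising and quality assessment for light-sheet
    Raman microscopy Z-stacks. Implements a Deep Image Prior encoder-decoder
    denoiser fitted per slice with early stopping, the surrounding pre- and
    post-processing chain (background subtraction, median filtering, circular
    region-of-interest masking, contrast-limited adaptive histogram
    equalization, grayscale morphology, Fourier band-pass filtering), the four
    validation metrics (PSNR, SSIM, RMSE, Fourier Ring Correlation), iterative
    Savitzky-Golay baseline correction and band assignment for Raman spectra,
    3D Z-stack reconstruction with maximum intensity projections, analytic
    optical calculators for the instrument design equations, and a synthetic
    spheroid phantom generator so the whole pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
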