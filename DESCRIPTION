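Package: ctdenoise
Title: Hybrid Wavelet-Bilateral Denoising for CT Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Denoising toolkit for single-channel CT images built around a
    hybrid method that applies bilateral filtering to the low-frequency
    (approximation) band of a multilevel 2D discrete wavelet decomposition and
    adaptive shrinkage thresholding (hard, soft, compromise and improved
    rules; universal and BayesShrink threshold selection) to the
    high-frequency detail bands.  Ships an analytic Shepp-Logan head phantom
    generator, seeded Gaussian, salt-and-pepper and speckle noise injectors,
    bilateral and non-local-means baseline denoisers, full-reference image
    quality metrics (MSE, PSNR, SSIM) and a benchmark runner that evaluates
    denoisers over grids of noise levels with tidy tabular output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    rlang,
    withr,
    png,
    tiff,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
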