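Package: aaaseg
Title: Denoising, Segmentation and Severity Grading of Abdominal Aortic
    Aneurysm CT Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable re-implementation of a CT image-analysis pipeline for
    abdominal aortic aneurysm (AAA) severity grading. Provides a synthetic
    vessel-phantom cohort generator, a signal-dependent Poisson-Gaussian noise
    model with ROI-based SNR calibration, a four-filter denoising bank
    (average, median, Wiener, and median-modified Wiener), a compact U-Net
    trained with mean-squared-error loss implemented in 'RcppArmadillo',
    a segmentation-quality metric suite (Matthews correlation, Dice, Jaccard,
    mean surface distance, PSNR, ICC(2,1), one-way ANOVA), and Hough-circle
    diameter measurement feeding a three-tier (low/moderate/high risk)
    severity classifier with confusion-matrix analytics. All stages operate
    on normalized [0,1] grayscale slices with known pixel spacing and are
    reproducible from a single master seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
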