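Package: fetalbw
Title: Automated Fetal Biometry and Birth-Weight Estimation from
    Ultrasound-Like Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating fetal birth weight from two-dimensional
    ultrasound-style images.  Provides a synthetic phantom generator with
    known ground truth, wavelet soft-threshold denoising with PSNR and SSIM
    image-quality metrics, automated measurement of head circumference,
    biparietal diameter, abdominal circumference (ellipse fitting) and femur
    length (minimum-area rectangle fitting), two published linear
    birth-weight models for an Ethiopian cohort, the model-development
    statistics (sample size, Pearson predictor screening, multiple linear
    regression with ANOVA, collinearity and Durbin-Watson diagnostics) and
    percentage-error model evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    grDevices,
    png,
    tiff,
    jpeg
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    car,
    lmtest
Config/testthat/edition: 3
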