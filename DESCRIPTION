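Package: hsifoul
Title: Hyperspectral Imaging Pipeline for Quantifying Marine Biofouling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and quantifying marine biofouling on coated
    test panels from staring-type hyperspectral images. Implements reading and
    writing of ENVI-convention hypercubes, a radiometric forward simulator of a
    liquid-crystal-tunable-filter imager with LED illumination and water-column
    attenuation, pixel-wise two-point (dark/bright field) reflectance
    calibration with Savitzky-Golay spectral smoothing, annotated spectral
    library construction with coarse and fine class schemes, standardized
    principal component analysis, a single-hidden-layer rectified-linear
    ("wide") neural network pixel classifier, and confusion-matrix and
    per-class coverage reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
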