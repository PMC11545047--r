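Package: hsigrade
Title: Vis-NIR Hyperspectral Defect Grading of Fruit with PLS-DA and
    Repeated Double Cross-Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometric pipeline for grading fruit defects from
    visible-near-infrared (400-1000 nm) hyperspectral images. Provides a
    seeded simulator for per-fruit reflectance spectra and hyperspectral
    cubes with ground-truth masks; mean-spectrum extraction with glare and
    defect-edge exclusion; composable train/test-aware spectral
    pre-processing (standard normal variate, multiplicative scatter
    correction, Savitzky-Golay derivatives, mean centering); from-scratch
    PCA, PLS-DA on class-indicator matrices, and greedy covariance-based
    variable selection (CovSel); a repeated double cross-validation engine
    with inner-loop model selection and stability-based wavelength
    selection; and confusion-matrix performance reporting
    (sensitivity, specificity, accuracy, mean class error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
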