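Package: spectvoi
Title: Volumetric Quantification of Cardiac I-123 MIBG SPECT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volume-of-interest (VOI) quantification of cardiac I-123 MIBG
    SPECT and planar acquisitions. Rasterizes ellipsoidal and box-shaped VOIs
    in physical millimetre coordinates, extracts count statistics, and computes
    decay-corrected uptake indices: heart-to-mediastinum (HM), myocardial
    wall-to-mediastinum (MM) and wall-to-lumen (ML) ratios, washout rates, and
    organ-specific washout. Includes the planar-image counterpart (2D ROI mean
    counts, planar HM and washout), reproducibility statistics (paired
    coefficient of variation, ANOVA-based intraclass correlation, one-sample
    t-test of absolute differences, correlation and stepwise regression), and
    a synthetic digital thorax phantom with configurable organ uptake,
    biological washout, physical decay, Gaussian point-spread blur and Poisson
    noise for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
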