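Package: icgquant
Title: Quantitative Analysis of Indocyanine Green Fluorescence Angiography Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of time-fluorescence curves from
    indocyanine green (ICG) near-infrared fluorescence angiography. Provides a
    perfusion-kinetics simulator for cohorts of region-of-interest (ROI)
    time-intensity curves and greyscale frame stacks; ROI trace extraction
    ("digital biopsy" sampling); quality control for acquisition artifacts
    (detector saturation plateaus, double-bolus twin peaks); Savitzky-Golay
    smoothing and peak normalization; curve-milestone feature extraction
    (time to first peak, time ratio, upslope, fixed-horizon downslopes,
    kurtosis); imputation of interrupted time series (K-nearest-neighbour
    within training tables, exponential-tail extrapolation for single test
    curves); and cross-validated two- and three-way tissue classification
    with AUC-ROC reporting, including an incremental-downslope feature
    experiment and a truncation-and-impute inference simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    pROC,
    caret,
    randomForest,
    nnet,
    e1071,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
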