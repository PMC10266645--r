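Package: somspec
Title: Soil Organic Matter Prediction from VNIR Spectra with Spectral
    Indices and CARS Band Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Chemometric pipeline for estimating soil organic matter (SOM,
    g/kg) from visible and near-infrared (350-2500 nm) diffuse reflectance
    spectra. Implements Savitzky-Golay smoothing and the standard soil
    spectral representations (log10(1/R), continuum removal, first
    derivative); exhaustive two-band spectral-index optimisation (DOA, DI,
    RI, NDI) against SOM via Pearson correlation maps; competitive adaptive
    reweighted sampling (CARS) characteristic-band selection over partial
    least squares submodels; Kennard-Stone calibration/validation
    partitioning; random forest, linear support vector regression, deep
    neural network and PLS regression model families with grid-searched
    10-fold cross-validation; and an evaluation suite (R2, RMSE, RPD with
    the Chang classes, Lin's concordance correlation coefficient). A
    synthetic soil-spectra generator with known SOM dependence makes every
    stage testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    knitr,
    rmarkdown
Config/testthat/edition: 3
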