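Package: leafNIR
Title: NIR Chemometrics for Antioxidant Phenotyping of Blueberry Leaves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Near-infrared (NIR) diffuse-reflectance chemometrics for
    predicting antioxidant parameters (total phenolic content, total
    flavonoid content, total antioxidant capacity) of Vaccinium leaf
    powders. Provides a synthetic spectra generator with the sampling
    structure of a multi-season, multi-region cultivar study, spectral
    preprocessing (standard normal variate, Savitzky-Golay derivative,
    mean centering), NIPALS PLS1 calibration with grouped leave-one-out
    cross-validation, exhaustive spectral-region combination search,
    calibration figures of merit (RMSEC/RMSECV/RMSEP, R-squared, range
    error ratio) with quality classification, season/region
    transferability analysis, and wet-chemistry standard-curve and
    dilution arithmetic with packaged reference tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
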