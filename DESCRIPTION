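Package: imsvoc
Title: GC-IMS Volatile Organic Compound Discrimination Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing and cross-validated classification of
    gas chromatography-ion mobility spectrometry (GC-IMS) spectra for
    volatile organic compound (VOC) profiling studies. Generates synthetic
    two-dimensional retention x drift intensity maps with planted class
    effects, implements the crop / reactant-ion-peak subtraction / static
    threshold preprocessing chain, runs a leakage-guarded k-fold
    cross-validation with Wilcoxon rank-sum feature selection and sparse
    logistic regression or gradient-boosted tree classifiers, and reports
    ROC diagnostics (AUC with DeLong or Hanley-McNeil confidence intervals,
    Youden-optimal cut-off, sensitivity, specificity, PPV, NPV) together
    with the Hanley-McNeil confidence-interval-width sample-size
    calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    xgboost,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
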