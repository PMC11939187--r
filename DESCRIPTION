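Package: maldiDx
Title: MALDI-TOF Serum Peptidome Processing, Biomarker Screening and
    Diagnostic Model Validation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for MALDI-TOF serum peptidome
    diagnostics. Provides spectrum preprocessing (Savitzky-Golay
    smoothing, moving-median despiking, white top-hat baseline removal),
    peak detection with greedy ppm-tolerance cross-sample alignment into
    a relative-area feature matrix, volcano-style differential peptide
    screening, benchmarking of eight classifiers under stratified
    cross-validation, consensus feature selection from Gini importances,
    kernel SHAP and LIME-style attributions, clinical-utility validation
    (Youden-optimised ROC thresholds, decision-curve analysis), and
    unsupervised concordance checks (bisecting K-means, BIRCH, Rand
    index, adjusted mutual information). A synthetic cohort generator
    with known ground truth supports validation in the absence of
    deposited patient spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    signal,
    e1071,
    randomForest,
    rpart,
    class,
    xgboost,
    pROC,
    kernlab,
    Rtsne,
    uwot,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    mzR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: MassSpectrometry, Proteomics, Classification, Clustering
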