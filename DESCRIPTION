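Package: vtwarn
Title: Heart-Rate-Variability Warning System for Ventricular Tachyarrhythmia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build and evaluate short-horizon warning systems for
    ventricular tachyarrhythmia from implantable-device R-R interval buffers.
    Provides annotated tachogram I/O and ectopy cleaning, time-domain,
    frequency-domain (Lomb periodogram band powers) and nonlinear (detrended
    fluctuation analysis, Hjorth parameters) heart-rate-variability features,
    principal component analysis of pre-event tachogram windows with
    Gavish-Donoho optimal hard thresholding of singular values, and a
    balanced, repeatedly resampled random-forest / linear-SVM evaluation
    protocol with permutation importances and rank-based group tests. A
    calibrated two-class synthetic cohort generator makes the full pipeline
    reproducible without access to clinical device downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
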