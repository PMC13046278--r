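Package: iohcast
Title: Real-Time Forecasting of Intraoperative Hypotension from Vital-Sign Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for forecasting intraoperative hypotension (IOH) from
    minute-resolution vital-sign time series. Implements the full study
    pipeline: reading and grid-alignment of per-case monitor records,
    plausibility filtering, percentile truncation and imputation, horizon
    labeling of 1-minute epochs, a Transformer encoder classifier trained
    with a composite focal + pairwise AUC-ranking loss (compiled
    forward/backward pass), a gradient-boosted benchmark on derived window
    features, discrimination and calibration evaluation with bootstrap
    confidence intervals, per-minute alert simulation, and a nested
    exposure analysis relating depth-weighted hypotension burden
    (mmHg.min below MAP thresholds) to postoperative acute kidney injury
    and acute kidney disease via KDIGO/ADQI creatinine staging and
    logistic regression. A synthetic vital-sign and renal-cohort generator
    with ground-truth logs makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
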