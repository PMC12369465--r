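Package: ctgtime
Title: Time-Varying Association Analysis of Cardiotocographic Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how cardiotocographic (CTG) features relate to
    labor outcome as a function of time to delivery. Provides a seeded
    synthetic cohort generator with controllable feature archetypes, a
    rule-based fetal heart rate event detector and per-epoch feature
    extractor (entropy, spectral band power, phase-rectified signal
    averaging, classical fetal heart rate variability indices),
    histogram-binned mutual information and conditional mutual information
    estimators, stratified Monte-Carlo permutation tests with
    Benjamini-Hochberg false discovery rate control, a feature taxonomy by
    time-invariant versus time-varying association, and time-resolved
    Kolmogorov-Smirnov discriminability with optimal thresholds and
    bootstrap variability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
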