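Package: tssentropy
Title: Bias-Corrected Entropy of Transcription Start Site Distributions and
    Chromatin-Feature Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the "width" of a promoter's transcription start site
    (TSS) distribution from CAGE tag counts as the Shannon entropy of an
    assumed Gaussian initiation model. Provides a simulated reference matrix
    (SDEM) for maximum-likelihood correction of the small-sample bias of the
    histogram entropy estimator, exhaustive k-feature linear-model selection
    with cross-validated Pearson correlation and BIC, k-means classification
    of histone marks into nucleosome-correlated (Class I) and uncorrelated
    (Class II) groups, and the cross-class ("bivalent-like") two-feature model
    comparison. A synthetic-data module generates CAGE-like tags and planted
    chromatin feature pools so the whole pipeline runs and is validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
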