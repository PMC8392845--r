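Package: emgsynergy
Title: Muscle Synergy Analysis and Classification of Lower-Limb Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Non-negative matrix factorization (NMF) based muscle synergy
    analysis for multi-channel lower-limb surface electromyography (sEMG).
    Provides envelope preprocessing and goniometer-driven motion
    segmentation, multi-restart multiplicative-update NMF with
    variance-accounted-for (VAF) model order selection, synergy similarity
    quantification with outlier-robust representative synergies,
    time-domain feature extraction from synergy and activation matrices,
    two-stage Relief-F plus sequential floating forward feature selection,
    imbalance-corrected (ADASYN) random-forest classification of lower-limb
    motions and knee pathology status, and a synthetic cohort generator
    with planted synergy structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    randomForest,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
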