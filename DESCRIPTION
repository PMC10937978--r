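Package: whistlevessel
Title: Dolphin Whistle Detection, Clustering and Vessel-Presence Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Passive-acoustic analysis of bottlenose dolphin whistles and their
    non-linear response to vessel presence. Provides adaptive noise cancellation
    (NLMS line enhancement), band-pass and wavelet transient suppression,
    spectrogram computation, Viterbi ridge tracking of whistle contours,
    graph-affinity clustering of traces into whistles (basic, harmonic,
    multipath, continuation), per-whistle communication-rate features,
    vessel-presence labeling from interval logs, and leave-one-day-out SVM-RBF
    classification with ablation and ratio-of-means statistics. Includes a
    seeded synthetic acoustic-scene and dataset generator with full ground
    truth for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
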