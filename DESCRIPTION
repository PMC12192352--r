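Package: catrains
Title: Coactivation, Sequence, and Task-Modulation Analysis of Calcium Event Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of deconvolved calcium event trains from
    one-photon microendoscopic imaging of motor cortex. Computes per-cell
    event descriptors (rate, inter-event-interval CV, amplitude) with
    Wilcoxon comparisons and Benjamini-Hochberg correction; aligns
    fluorescence traces to behavioral events with per-trial Z-scoring
    against an inter-trial-interval baseline and classifies cells as
    direction-related or non-direction-related; quantifies pairwise
    coactivation with the Jaccard index standardized against a
    circular-shift null (Z-Jaccard); and detects precisely timed multi-cell
    event sequences validated against a circular-shift permutation null.
    Includes a synthetic-session generator with planted synchrony,
    sequences, and direction tuning for parameter-recovery testing, plus a
    config-driven pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
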