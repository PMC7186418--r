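Package: scqpcr
Title: Single-Cell qPCR Ct-Matrix Analysis of Regenerating Lung Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-cell qPCR cycle-threshold (Ct) matrices
    from microfluidic capture experiments, built around the post-pneumonectomy
    alveolar-duct regeneration study design. Provides Ct matrix input/output with
    detection censoring, limit-of-detection referenced log2 expression (Et),
    an authored t-distributed stochastic neighbor embedding (exact and
    Barnes-Hut gradients) with perplexity calibration, density-aware
    agglomerative clustering constrained to a fixed cluster count, projection of
    sorted-cell bulk expression profiles onto the single-cell map through a
    correlation similarity matrix, cluster-frequency time courses, per-cluster
    log2 fold-change marker rankings, Welch two-sample tests, and a seeded
    synthetic-cohort generator with ground truth that emulates the study design
    for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
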