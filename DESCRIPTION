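Package: hmmchip
Title: Hidden Markov Regression Models for ChIP-chip Enrichment Detection
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects probes enriched by chromatin immunoprecipitation on
    tiling arrays (ChIP-chip) with a two-state first-order hidden Markov
    model whose Gaussian emissions regress log-IP intensity on log-Input
    intensity, jointly across biological replicates. Parameters are
    estimated by the Baum-Welch algorithm from a principal-component
    initialization, and probes are classified as enriched when their
    posterior probability of the enriched state exceeds a user-chosen
    cutoff. A spatial-independence mixture variant, a simulator for the
    generative model, ROC/false-positive-rate evaluation utilities, and
    tab-delimited/BED input-output round out the toolkit.
License: GPL (>= 2)
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
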