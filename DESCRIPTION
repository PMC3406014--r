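Package: bcpseg
Title: Bayesian Change-Point Segmentation of ChIP-Seq Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide detection of ChIP-seq enrichment by an
    infinite-state Poisson-Gamma change-point model. Read counts per
    block are smoothed into per-position posterior mean densities by
    exact forward-backward Gamma-mixture recursions, accelerated by a
    bounded-complexity mixture (BCMIX) approximation; hyperparameters
    are estimated empirically (method of moments for the Gamma prior,
    grid-search maximum likelihood for the change probability). The
    posterior mean track is segmented into diffuse histone-modification
    islands or punctate transcription-factor peaks with summits, and
    candidates are validated against an input control by a Poisson
    test; empirical FDR is computed by sample inversion. Includes a
    synthetic read simulator, BED/bedGraph input and output, evaluation
    metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
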