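Package: cladesift
Title: Discovery and Validation of Lineage-Specific Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end, desk-scale pipeline for discovering
    lineage-specific (e.g. bilaterian-specific) gene families from
    multi-species protein data: six-frame ORF extraction and filtering,
    OrthoMCL-style similarity graph construction with native Markov
    clustering, taxonomy-aware last-common-ancestor assignment and
    clade-composition filters, reciprocal best-hit validation with
    profile-profile searches, transcription-factor enrichment statistics,
    and protein-protein interaction network summaries. Includes a
    gene-family birth/loss simulator on a labelled species tree so every
    stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    broom,
    mclust,
    optparse,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
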