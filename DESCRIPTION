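Package: promotif
Title: Promoter Motif Enrichment, Co-Expression Clustering and
    Cross-Species Motif Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for regulatory-genomics analysis of co-expressed
    gene sets. Extracts strand-aware promoter windows around transcription
    starts, scans them with TRANSFAC-format position weight matrices using
    frequency-calibrated log-odds thresholds, and tests each matrix for
    binding-site enrichment in a gene set against a reference promoter
    sample (Fisher exact test on promoter counts, binomial test on site
    frequency, and a confidence-interval-adjusted fold enrichment maximised
    over score thresholds). Differentially expressed genes are clustered
    with an MCODE-style graph algorithm on a rank-correlation co-expression
    network, promoter motifs are mapped into multiple alignments of
    ortholog promoters to assess positional conservation across species,
    and qPCR Ct tables are converted to relative expression by the 2^dCt
    method with nonparametric group comparisons. A synthetic-data module
    generates every input with planted ground truth so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
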