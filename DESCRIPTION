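Package: cernet
Title: Competing Endogenous RNA Network Inference from Tissue-Exosome Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers lncRNA/miRNA/mRNA competing endogenous RNA (ceRNA) axes
    from FPKM-scale expression matrices of tissue-derived exosomes. Provides
    Mann-Whitney differential expression with abundance and fold-change
    filters, cis (genomic window) and trans (co-expression) lncRNA target
    assignment, multi-source miRNA-target evidence integration,
    correlation-constrained tripartite network assembly with hub-degree
    analysis and cross-subtype intersection, Kaplan-Meier log-rank screening
    of network miRNAs for prognostic value, and a synthetic-data generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    broom,
    jsonlite,
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
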