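Package: suppnet
Title: Suppressor-Line Transcriptome Comparison and Parsimonious Subnetwork
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative transcriptome analysis of a mutant line and its
    suppressor lines: moderated differential-expression calling with
    fold-change and FDR thresholds, classification of genes into restored,
    compensatory and non-restored groups with strict cores, marker-gene
    concordance, empirical-null gene scoring and product edge weighting,
    parsimonious subnetwork inference by bounded k-best path search with a
    penalty sweep and Jaccard stability selection, hypergeometric gene-set
    enrichment, ANOVA with Tukey compact-letter displays, and a synthetic-data
    generator with planted differential expression and planted network
    modules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    limma,
    MASS,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
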