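Package: orcnv
Title: Population-Scale Copy-Number Analysis of the Olfactory Receptor Repertoire
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for population-scale copy-number variant (CNV)
    analysis of a gene repertoire, modelled on array-based studies of the
    human olfactory receptor (OR) subgenome. Segments per-sample log2-ratio
    probe tracks into CNV calls with a Gaussian hidden Markov model and a
    robust multiple-threshold caller, genotypes copy-number polymorphic
    regions across samples, applies LOD/size/probe retention and sample QC
    rules, validates call sets by reciprocal overlap and the Jaccard
    statistic, annotates calls against an intact/pseudogene catalogue,
    detects recurrent (hotspot) versus rare events with interval-graph
    clique analysis, tabulates cross-population sharing and conserved
    breakpoints, classifies trio events as inherited or de novo, and
    screens 1 kb breakpoint flanks against a genome panel by local
    alignment to separate orthologous from paralogous (derived) sequence,
    feeding UPGMA and neighbor-joining trees. A synthetic-data module
    generates probe tracks, trios, annotations and flank genome panels
    with known ground truth so every stage is testable without raw arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
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
    xml2
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
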