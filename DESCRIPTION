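Package: alusirna
Title: Annotation Cascade and Profiling of Alu-Derived Endogenous siRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and quantifying endogenous small interfering
    RNAs (endo-siRNAs) derived from Alu short interspersed elements in small
    RNA sequencing libraries. Implements a hierarchical read-annotation
    cascade (rRNA, tRNA, miRNA, repeat consensus, snoRNA, transcript, genome)
    with ungapped both-strand alignment under a bounded mismatch count,
    strand-resolved length distributions and consensus positional profiles in
    counts per million, an exclusion-normalized differential statistic for
    knockdown versus control comparisons, zero-mismatch mapping of in vitro
    DICER cleavage products onto inverted-Alu hairpins, a target-gene screen
    based on single-copy 3'UTR Alu elements and siRNA seed complementarity,
    and a synthetic-data generator with per-read ground truth that emulates
    DICER cleavage of inverted-Alu hairpin stems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
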