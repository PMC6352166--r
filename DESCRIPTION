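Package: issweep
Title: Insertion Sequence Annotation, CRISPR Repeat Filtering and
    Insertion-Site Calling for Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects full and partial insertion sequence (IS) copies in
    bacterial replicons with a self-contained seed-and-extend search at
    nucleotide and translated (six-frame) level, classifies transposase
    activity from ORF integrity and DDE/DEDD motif content, separates
    IS-derived CRISPR repeat arrays from genuine IS scars, computes
    per-replicon abundance and density statistics, and calls novel IS
    insertion sites from soft-clipped read alignments across strains.
    Includes a ground-truthed simulator for multi-replicon genomes,
    derived strains, and junction-spanning read alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    purrr,
    Rcpp,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
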