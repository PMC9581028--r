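Package: startfinder
Title: Alignment-Evidence Prediction of Prokaryotic Gene Starts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the translation initiation site of a prokaryotic gene from
    conservation patterns in multiple alignments of homologous longest open
    reading frames (LORFs). Homologs are filtered by pairwise alignment coverage
    and by Kimura two-parameter nucleotide distance into an informative window,
    a dual-layer (protein and codon-resolved nucleotide) alignment is built, and
    the start codon is selected by a three-step conservation procedure using a
    block identity score, a candidate-neighborhood start-conservation score, and
    an intergenic-distance conservation statistic for gene overlaps. Also
    provides an exact-agreement combiner for integrating an independent ab
    initio annotation, 3'-anchored accuracy, error and coverage evaluation
    metrics, and a sequence-evolution simulator that generates homologous LORF
    families with known true starts for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
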