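Package: concatseq
Title: Simulation, Deconcatenation and Variant Readout for Concatemer
    Amplicon Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for concatemer-based single-molecule amplicon
    sequencing (ConcatSeq-style libraries), in which short adapter-flanked
    amplicons are joined by Gibson assembly into long concatemers and read
    as circular consensus sequences.  Provides a library-geometry model
    (n-mer size law, adapter design constraints, scale-up estimates), a
    synthetic read simulator with a ground-truth sidecar, deconcatenation
    of reads by greedy approximate adapter scanning in both orientations,
    fragment classification (hairpin-ligation remnants, expected-size and
    oversized populations, truncated terminal adapters), semi-global
    alignment of fragments to an amplicon panel with spacer soft-clipping,
    hybrid-fragment detection with relaxed-rescan rescue, pileup-based
    allele-frequency extraction, and run-level statistics such as the
    degree of concatenation and the on-target rate.  All user-facing
    functions take and return tibbles so pipelines compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
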