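Package: mirvar
Title: Quantification and Variation Analysis of MicroRNAs from Small RNA
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A pipeline for quantifying known and novel microRNAs from
    small RNA sequencing libraries, with detailed variation analysis.
    Reads are quality filtered, adapter trimmed with one tolerated error
    base, collapsed, and aligned to precursor hairpins with a
    penalty-capped semi-global aligner that allows mismatches, indels and
    free terminal soft clips.  Counts of multi-mapping reads are divided
    evenly over their best-priority mappings so no read is counted more
    than once.  Downstream modules classify isomiRs (end shifts, internal
    edits, 3' non-templated nucleotide addition including A-to-G editing
    candidates), aggregate counts by miRNA family, detect 5p/3p arm
    switching between treatments, catalogue genome-aligned reads by
    annotated biotype, and nominate novel precursor miRNAs from perfect
    genome read stacks.  A deterministic synthetic-data generator
    provides closed-loop fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
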