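Package: srnascape
Title: Small RNA Locus Discovery, IsomiR Classification and Phasing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated toolkit for multi-library plant small-RNA
    analysis: read collapsing, TPM normalization and a staged filtering
    cascade; miRNA precursor discovery with strand/abundance-bias gates and
    a maximum-base-pairing hairpin folder; classification of isomiRs into
    seven variant classes with end-nucleotide composition summaries; an
    exact small-count (Audic-Claverie) differential-expression test;
    entropy/Z-score tissue-specificity calling with a one-step Tukey
    biweight (ROKU-style modH); phased-siRNA (PHAS) locus detection with a
    hypergeometric phasing p-value and trigger assignment; and
    singleton/duplicate classification with chi-square ratio tests. A
    synthetic-data generator emulating a 14-tissue maize small-RNA study
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    rtracklayer,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
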