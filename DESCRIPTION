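Package: klrseq
Title: Tissue-Specific Regulatory Code Words from Enhancer DNA by Sparse
    Gapped k-mer Logistic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies tissue-specific regulatory information in enhancer
    DNA sequences. Sequences are mapped to gapped k-mer "code word"
    features (reverse-complement collapsed), and class-weighted
    L1-penalized logistic regression is fitted with a just-in-time SAGA
    solver whose penalty is chosen by a leapfrog search so that a
    prescribed number of features is selected. Includes constructors for
    tissue-bipartition datasets from per-tissue regulatory-element
    intervals, nested cross-validation with precision-recall evaluation,
    extraction of stable tissue-specific code words, ATAC-seq footprint
    aggregation around code-word occurrences, sliding-window genome
    prediction tracks, and a synthetic-data generator with planted motifs
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
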