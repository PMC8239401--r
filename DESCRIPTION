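Package: bidirtss
Title: Discriminating Promoter and Enhancer Sequences at Bidirectional
    Transcription Start Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies promoter versus enhancer sequences from fixed-length
    DNA windows centred on the midpoint of a bidirectional transcription start
    site (TSS) pair. Implements a constrained family of two-layer convolutional
    networks (coupled max-pool sizes whose product is fixed, so the fully
    connected input size is invariant), trained by mini-batch Adam on binary
    cross-entropy and evaluated by fivefold cross-validation with AU-ROC;
    gradient-based saliency maps with per-sequence normalized importance scores
    and a 1/length importance threshold; a hexamer-frequency RBF-SVM baseline
    with grid search; GC-content characterization of regions, positional
    slices and saliency-selected positions; and a synthetic bidirectional-TSS
    sequence generator with class-dependent global and downstream GC
    composition and optional planted motifs, so that the whole pipeline is
    testable without external genomics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    kernlab,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
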