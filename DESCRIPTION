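Package: crossenhancer
Title: Cross-Species Generalization of k-mer Spectrum Enhancer Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains cost-weighted linear support vector machines on k-mer
    spectrum features to distinguish tissue enhancers from matched genomic
    background, quantifies how well classifiers trained in one species
    generalize to others via relative auROC/auPR statistics, and interprets
    the most predictive k-mers by exact-enumeration matching against
    transcription-factor motif models, with permutation and contingency-table
    statistics for motif sharing and expression enrichment. Includes matched
    negative-region samplers (length/chromosome, GC, GC+repeat, flanking) and
    a deterministic multi-species synthetic genome simulator with planted
    motif instances, repeats, orthologous enhancers and TF-expression tables
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    e1071,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
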