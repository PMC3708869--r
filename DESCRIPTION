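Package: cyclescan
Title: Predicting Cell Cycle Regulated Promoters from TF Binding and Motif Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts cell cycle regulated genes and transcription start sites
    from promoter features. Computes TIP (Target Identification from Profiles)
    regulatory scores from per-base ChIP-seq signal around transcription start
    sites, MATCH-style position-weight-matrix similarity scores over promoter
    sequences, and combines both feature classes in a Random Forest classifier
    with Gini and permutation importance, feature-ablation curves, phase-specific
    models, genome-wide TSS prediction with an empirical false discovery rate
    estimated from artificial random TSS controls, and downstream enrichment
    statistics. Ships a fully parameterised synthetic-data generator with planted
    binding peaks, motif instances and an expression confounder, so the entire
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
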