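Package: rloopshift
Title: Differential R-Loop Landscape Analysis for Strand-Specific DRIPc-Seq
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Strand-specific analysis of R-loop mapping (DRIPc-seq-like)
    coverage between two conditions: two-state hidden Markov model peak
    calling with a standard and a high-sensitivity decoding mode,
    negative-binomial differential signal testing with median-of-ratios
    normalization and trend-shrunken dispersions, classification of genes
    into R-loop gain (RLG) and R-loop loss (RLL) classes, matched-control
    Monte-Carlo enrichment against chromatin feature sets, distance and
    fold-change-binned covariate analyses, strand-aware metagene and
    anchor-centered profiles, replication-timing phase assignment, and
    segmentation of OK-seq replication fork directionality into initiation
    zones. Ships a deterministic synthetic-data generator that plants
    gains, losses, chromatin context, and replication structure with known
    ground truth so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
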