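Package: pirnatools
Title: Pachytene piRNA Cluster Profiling from Small RNA and CLIP Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying PIWI-interacting RNA (piRNA) production
    from genomic piRNA clusters in small RNA sequencing libraries. Implements
    adapter clipping and length-window preprocessing, ungapped one-mismatch
    read matching with sequential-exclusion annotation against an ordered
    category hierarchy (piRNA clusters, coding RNA, non-coding RNA, repeats,
    intron, other), microRNA-proxy normalization of paired wild-type/mutant
    libraries, per-cluster abundance ranking and fold-change analysis,
    within-precursor positional analyses (5'-window versus full-length fold
    change with a paired t-test, per-position density tracks, 100-bin
    metagene profiles), and a CLIP-read branch with fragment signatures and
    piRNA co-density correlation. A seeded scenario simulator generates
    reference sequences, read libraries and truth tables with the
    statistical structure of adult-testis piRNA populations so that every
    pipeline stage can be verified at desk scale.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    methods,
    IRanges,
    Rcpp,
    jsonlite,
    rtracklayer,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
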