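Package: mirphase
Title: Small-RNA Annotation, miRNA Discovery and Flowering-Phase
    Expression Analysis for Plant Deep-Sequencing Libraries
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for plant small-RNA sequencing
    studies without biological replicates. Collapses reads to unique
    tags, matches them perfectly to a genome, assigns each tag a single
    annotation category through a fixed-priority cascade (structural
    RNA, repeats, exons/introns, known miRNAs), quantifies known miRNAs
    with templated +/-2-nt end variants, predicts novel miRNA
    candidates from hairpin secondary structure under plant-miRNA
    annotation criteria, scores miRNA-target complementarity with a
    seed-weighted penalty scheme, maps 5'-RACE cleavage sites, and
    tests between-library differential expression with a conditional
    count statistic feeding a flowering-phase (F/E/N) classifier. A
    fully deterministic synthetic-data generator plants ground truth at
    every stage so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
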