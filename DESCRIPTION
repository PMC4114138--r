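Package: regulonscan
Title: Promoter Motif Enrichment and Regulon Overlap Analysis for
    Knockdown Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for identifying candidate transcription
    factors behind a repressive sub-signature of a silenced regulator.
    Implements empirical-Bayes moderated-t differential expression of a
    knockdown time course with Benjamini-Hochberg correction, strand-aware
    upstream promoter windows from UCSC-dialect gene models, counting of
    conserved transcription-factor binding sites per promoter, the binned
    motif-count versus log-fold-change Pearson correlation statistic,
    exact hypergeometric gene-set overlap tests, and distribution-free
    permutation and rank statistics for two-arm tumor growth curves.
    Includes seeded synthetic-data generators with planted regulons so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
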