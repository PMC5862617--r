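Package: islandmeth
Title: CpG-Island Differential Methylation with Cross-Platform Probe Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probe-level differential methylation analysis of Illumina
    BeadChip beta values with signed DiffScores and permutation-based false
    discovery rates; a CpG-island probe-enrichment algorithm that validates
    sparse-platform (27K-like) island findings against dense-platform
    (450K-like) data using direction-consistency, probe-concordance,
    effect-size and probe-count criteria; unsupervised hierarchical
    clustering of samples on significant loci; delta-delta-CT relative
    expression analysis for qRT-PCR; and median-expression-split
    Kaplan-Meier survival comparison. Includes a synthetic-data generator
    producing paired sparse/dense beta matrices with planted island-level
    effects, CT tables and survival tables, so the full pipeline is
    testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
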