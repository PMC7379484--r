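Package: markstates
Title: Chromatin State Dynamics from Histone Mark Peaks, Accessibility, and
    Expression in a Two-Tissue Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream integration of H3K27me3 and H3K4me3 ChIP-seq peaks,
    DNase I hypersensitivity, and gene expression for a two-tissue contrast
    (dedifferentiated callus versus seedling). Classifies peaks into six
    genomic region classes, assigns marks to genes through a 2-kb-upstream
    plus gene-body window, calls tissue-differential deposition, computes
    scaled meta-gene and TSS-centred signal profiles, calls per-gene
    active/bivalent/repressed chromatin states and the seven callus-to-
    seedling state transitions, performs hypergeometric gene-set enrichment
    with Benjamini-Hochberg correction, calls tissue-preferential expression
    from a multi-tissue panel by Z-score, clusters genes on multi-mark
    signal with k-means, and ships a synthetic-data generator with planted,
    machine-readable truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    limma,
    mclust,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
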