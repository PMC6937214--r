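Package: oxichrom
Title: Integrative Chromatin Analysis of H3K4ox ChIP-seq and ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nucleotide-resolution integration of H3K4ox ChIP-seq peaks with
    chromatin-state segmentations, lamin-associated domains and ATAC-seq
    accessibility data. Provides Fisher exact-test enrichment of peak
    nucleotides across grouped ChromHMM states, classification of significant
    ATAC peaks by H3K4ox overlap, summit-aligned signal matrices and
    control-summit-normalized metaprofiles, replicate correlation of per-base
    coverage tracks, TMM-normalized differential expression summaries for
    transposable-element count tables, and distance-based linking of
    differentially expressed genes to accessible peaks. Ships seeded synthetic
    data generators that plant recoverable structure in every input so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    data.table,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
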