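Package: chipaffinity
Title: Comparing Transcription Factor Genome Occupancy with Intrinsic
    DNA-Binding Affinity
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for asking whether the genome-wide occupancy of a
    sequence-specific transcription factor, measured by ChIP-seq, is
    explained by its intrinsic DNA-binding affinity, measured by universal
    protein-binding microarrays (PBM).  Builds strand-aware coverage
    tracks from aligned reads, computes TSS-anchored metagene profiles
    and rank-ordered heatmap matrices, quantifies pairwise track
    similarity with a bounded overlap score, calls peaks by greedy summit
    selection with contributing-read heights, normalizes
    reverse-complement-collapsed 8-mer PBM intensities into relative in
    vitro occupancies, scans genomes for high-affinity E-box cores, and
    runs the motif-enrichment statistics (ROC/AUC, rank tests, Fisher
    tests) that contrast occupied regions with accessible background.  A
    synthetic-data generator with planted ground truth makes the whole
    pipeline testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    pROC,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
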