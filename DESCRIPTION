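Package: plastichrom
Title: Chromatin-State Dynamics, Cell-State Programs and Drug Synergy in
    Lineage-Plastic Prostate Cancer Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline linking EZH2-driven chromatin dynamics to
    cell-state programs and drug-combination synergy. Classifies promoters
    into four chromatin states (Active, Repressed, Bivalent, Unmarked) from
    H3K4me3/H3K27me3 peak calls, tracks state transitions between
    conditions and ranks transition classes against differential
    expression; scores gene programs and master-regulator transcription
    factor modules in single-cell data with pseudotime smoothing and
    permutation-based pre-ranked GSEA; computes Bliss-independence synergy
    landscapes from dose-response plates; and nominates bait-specific
    interactors from spectral-count tables. A synthetic-data module
    generates every input with planted ground truth so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
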