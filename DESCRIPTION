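Package: csabmine
Title: Mining and Classification of Bacterial CS-Alpha-Beta Defensins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Motif-based discovery and structural-archetype classification of
    bacterial cis-defensins. Implements the cysteine-spacing filter cascade
    (size band, CX(2,18)CX(3)CX(2,12)CX(4,17)CXC framework scan, secretion
    gate), cysteine-framework and disulfide-topology feature extraction,
    rule-based assignment to five structural classes, greedy redundancy
    clustering on a from-scratch global aligner, cysteine-anchored class
    alignments, and a structural-verification toolkit (Kabsch superposition,
    NMR ensemble RMSD, distance-restraint tallies, in-silico PCR). A seeded
    synthetic-data generator emits labelled precursors and stage-targeted
    decoys so every pipeline stage is testable without external databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
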