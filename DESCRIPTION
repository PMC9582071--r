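Package: mrioverlap
Title: Set-Similarity Analysis of MRI Protocol Usage and Protocol-Tree
    Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much information the ICD-10-coded admitting
    diagnosis carries for MRI protocol selection, and how heterogeneous the
    protocol trees of different MRI scanners are. Implements the Jaccard
    index, the overlap (Szymkiewicz-Simpson) coefficient and a complement
    overlap coefficient over sets of admitting-diagnosis code combinations;
    multi-label statistics (cardinality, density, diversity); a deterministic,
    rule-based MR sequence-name standardizer driven by acquisition parameters
    (TR, TE, TI, technique, orientation); cross-scanner protocol-tree
    comparison with a chi-square variability test; and a seeded synthetic
    generator for exam logs and protocol trees so every analysis stage is
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
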