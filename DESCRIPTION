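Package: netexpr
Title: Comparative Transcriptome Analysis via Pathway Net Expression and
    Self-Organizing Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for comparing tumor groups and cell-line
    groups against non-neoplastic controls from bulk RNA-seq count matrices:
    biotype-stratified expression filtering, per-group negative-binomial Wald
    tests with Benjamini-Hochberg correction, multi-group direction
    concordance analysis, pathway "net expression" scoring against a detected
    gene universe, and clustering of pathway dysregulation profiles on a
    hexagonal self-organizing map. Includes a seeded synthetic-data generator
    with planted fold changes and pathway archetypes so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
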