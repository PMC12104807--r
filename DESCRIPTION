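Package: dollopsin
Title: Dollo Parsimony Reconstruction of Opsin Gene-Family Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing gene-family gain and loss on rooted
    species trees under single-gain (Dollo) parsimony, built around the
    question of where Xenacoelomorpha sits in the animal tree. Ships the
    two competing species-tree hypotheses (Nephrozoa and Xenambulacraria),
    curated opsin-family and phototransduction-pathway presence/absence
    matrices, an event-enumeration engine with ancestral-repertoire and
    hypothesis-comparison queries, residue-homology classification at the
    conserved rhodopsin K296 lysine through multiple alignments, tiered
    similarity-search annotation filters, clade-level pathway-completeness
    aggregation, and seeded synthetic-data generators with ground-truth
    logs so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
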