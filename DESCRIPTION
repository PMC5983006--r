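Package: phyloinstab
Title: Phylogenetic Instability Scoring of Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconciles a multi-species gene-family tree against a species
    tree, partitions it into minimum instability groups (MIGs) by a two-phase
    parsimony and spread clustering procedure, and assigns every gene a
    phylogenetic-instability score. Includes a one-tailed Mann-Whitney U
    comparison of score distributions between sets of MIGs and a seeded
    simulator of gene-family evolution along a species tree for generating
    test fixtures with known ground-truth events.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
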