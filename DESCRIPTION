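Package: exomewalker
Title: Network-Guided Prioritization of Candidate Disease Genes in Exome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate disease genes in whole-exome variant data by
    combining a random-walk-with-restart proximity score over a protein-protein
    association network, seeded with a known disease-gene family, with a variant
    score built from population allele frequency and predicted pathogenicity.
    Includes mode-of-inheritance models (dominant, recessive with compound
    heterozygotes), a cross-validated logistic model that fuses the two scores,
    a spike-in benchmarking harness measuring top-k recovery of known disease
    genes, and deterministic synthetic-data generators (planted-module networks,
    background exomes, labeled variant sets) so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    vcfR,
    glmnet,
    pROC,
    jsonlite,
    tibble,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
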