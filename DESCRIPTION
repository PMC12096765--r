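Package: prsdual
Title: Polygenic Risk Scoring over Dense and Sparse Genotype Representations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes polygenic risk scores (PRS) from either a dense
    genotype matrix ingested from VCF or a sparse variant dataset that
    stores only non-reference calls plus homozygous-reference blocks, with
    configurable handling of missing genotype calls (exclusion versus
    homozygous-reference imputation). Parses and round-trips PGS Catalog
    scoring files, restricts scoring to QC-passed variants via an
    annotation table, and evaluates agreement between score sets with
    logistic association (odds ratio per standard deviation), rank-based
    AUC, Lin's concordance correlation coefficient, and empirical CDF
    comparison. Ships a seeded synthetic-cohort simulator and a
    command-line interface so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    graphics,
    grDevices,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
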