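Package: phenogeno
Title: Phenotype-Genotype Association Screening for Paired Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking clinical phenotypes to transcriptome changes in
    small paired tumor/control cohorts. Implements the paired differential-index
    (DI) statistic for FPKM-scale expression matrices with its adjusted
    fold-change transform and coverage-based gene selection, a clinical
    phenotype-phenotype Spearman correlation screen with Benjamini-Hochberg
    false-discovery-rate control, a gene-expression-versus-phenotype Pearson
    association screen, protein-protein-interaction induced-subgraph and
    connected-component analysis, hypergeometric gene-set overrepresentation
    testing, cohort group-comparison statistics, delta-delta-Ct relative
    quantification, and seeded synthetic-cohort generators with ground truth
    for validating every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
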