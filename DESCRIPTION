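Package: pbiScan
Title: Partition-Based Gene-Environment Interaction Scans for Quantitative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Nonparametric detection of gene-environment (GxE) interactions for
    quantitative traits in family data. Implements the partition-based
    interaction score: a total association score over the joint genotype x
    environment cells minus the larger of the two marginal scores, with
    significance assessed by global, within-pedigree (local), or residual
    permutation of the phenotype. Includes longitudinal covariate
    summarization and discretization, VCF and dosage-matrix input, a linear
    regression model comparator, a genome-scan driver with Bonferroni
    correction, and a pedigree-aware cohort simulator for type-I error and
    power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'partition-score.R'
    'covariates.R'
    'io.R'
    'lrm.R'
    'pbiScan-package.R'
    'permutation.R'
    'scan.R'
    'simulate.R'
    'power.R'
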