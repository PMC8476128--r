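Package: orgenrich
Title: Heritability Enrichment Analysis of Organellar Proteome Gene-Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for asking whether loci encoding organellar
    proteomes (mitochondrion, nucleus and its sub-compartments, other
    organelles) are enriched for the heritability of age-related traits.
    Provides systematic age-related trait prioritization from period
    prevalence, gene-set construction from subcellular localization evidence,
    a GWAS-catalog-style Fisher screen with an empirical resampling null on
    the enrichment count, competitive gene-level enrichment regression with
    technical covariates and constraint conditioning, a subsampling power
    framework, tau tissue-specificity and a cross-tissue eQTL-landscape
    model, mitochondrial DNA association testing with Firth-penalized
    logistic regression, latent-normal (tetrachoric and biserial) trait
    correlations, and LOEUF constraint-decile summaries. A seeded synthetic
    data module emulates every input table with planted effects so each
    stage can be validated against a known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
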