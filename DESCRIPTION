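Package: hipmodes
Title: Statistical Shape Modelling and Genetic Association for Hip Shape Modes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Landmark-based statistical shape modelling of the proximal femur
    from 2D (DXA-style) landmark configurations. Provides generalized
    Procrustes alignment, principal-component shape models ("hip shape
    modes", HSMs), projection of new cohorts onto a serialized reference
    model with reference-SD standardisation, candidate-SNP quality control
    (minor allele frequency, call rate, exact Hardy-Weinberg test) and
    additive linear association of allele dosages with mode scores under
    several covariate-adjustment models, reconstruction and SVG rendering of
    the shape change implied by per-allele effects, and a fully seeded
    synthetic-data generator (landmarks, genotypes, covariates, longitudinal
    cohorts) with a truth ledger so every stage is testable without access
    to restricted cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
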