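Package: vaxsig
Title: Innate Immune Signatures Predicting Vaccine Antibody Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A systems-vaccinology pipeline relating the early innate
    response to adjuvanted vaccination (gene-expression log fold changes,
    serum cytokines, C-reactive protein) to the magnitude, quality and
    persistence of the antibody response. Implements per-sample gene-set
    variation scoring of blood transcriptional modules, the data-cleaning
    and integration rules of the source workflow (probe collapse, IQR
    filtering, limit-of-quantification imputation, K-nearest-neighbour
    imputation, z-scaling), nested cross-validated LASSO and random-forest
    prediction of antibody features at multiple timepoints with
    predictability gating, correlation-cluster-corrected feature-importance
    ranking and aggregation, descriptive association analyses, and an
    adjuvant-group classifier with selection frequencies. A seeded
    synthetic-study generator with known ground truth makes every stage
    testable without access to restricted clinical-trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
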