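Package: canary
Title: Exemplar-Based Risk Stratification of Pure Ground-Glass Lung Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Voxel-level texture risk classification of segmented pure
    ground-glass lung nodules on computed tomography. Nine texture exemplars
    (9x9 Hounsfield-unit patches) are learned by affinity propagation
    clustering, every in-nodule voxel is labelled by its nearest exemplar,
    and labels are aggregated into low/intermediate/high risk components.
    Includes rank-based subtype statistics (Kruskal-Wallis, Conover-Iman,
    Spearman with Bonferroni correction), a diagnostic threshold sweep of the
    low-risk percentage with exact binomial confidence intervals, and a
    synthetic-data module that generates ground-glass nodule phantoms and
    per-subtype cohort tables so the full pipeline is testable without
    patient data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    png,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
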