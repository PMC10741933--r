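Package: cogage
Title: Successful Cognitive Aging Classification and Multimodal Phenotype Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for identifying a successful-cognitive-aging cohort from a
    multi-test cognitive battery and comparing image-derived phenotypes (IDPs)
    and demographic indicators between the resulting groups. Implements a
    PCA-derived generic cognitive score with dual-reference Z-standardization
    and a two-stage threshold cascade, head-size normalization and
    least-squares deconfounding of IDPs, normality-routed group tests
    (ANOVA, Mann-Whitney U, chi-square) with per-family Benjamini-Hochberg
    false-discovery-rate control, and a follow-up comparison against a
    middle-aged reference group. A latent-factor synthetic cohort generator
    with planted effects makes every stage testable without access-restricted
    biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
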