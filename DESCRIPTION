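Package: tksig
Title: Prognostic Tyrosine Kinase Expression Signature Discovery in
    Triple-Negative Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for discovering and validating prognostic
    gene-expression signatures from pooled multi-study breast cancer
    transcriptomic cohorts, centred on an 86-gene tyrosine kinase panel in
    triple-negative disease. Harmonizes studies by luminal-A-anchored
    z-score normalization, calls receptor status from bimodal ESR1/PGR/ERBB2
    expression, screens genes for disease-free survival association by Cox
    regression, selects a multigene signature by AIC stepwise search, builds
    a median-cutoff two-class risk classifier, quantifies non-randomness
    against a resampling null of random same-size signatures, and
    characterizes risk classes by empirical-Bayes moderated t differential
    expression and a nearest-centroid correlation score. Includes a
    synthetic multi-study cohort generator with known ground truth for
    calibration and power testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    mclust,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
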