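Package: metstab
Title: Genotype-by-Season Stability Analysis for Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stability analysis of replicated multi-environment (multi-season)
    trials for plant breeding selection, built around the additive main
    effects and multiplicative interaction (AMMI) model: pooled ANOVA with
    Levene homogeneity checking, SVD decomposition of the genotype-by-season
    interaction with signal/noise partitioning and per-axis significance
    tests, the AMMI stability index (ASI) and simultaneous selection index
    (SSI), value relative to the environment maximum (YREM), BLUP predicted
    genotype means with heritability and WAASB stability scoring, and a
    fresh-seed-dormancy screening layer (intensity-of-dormancy summaries,
    marker-phenotype concordance, donor selection). Includes a synthetic
    trial generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
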