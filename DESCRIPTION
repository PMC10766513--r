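Package: hetrep
Title: Multi-Laboratory Replicability Analysis for Heterogenized Study Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating whether heterogenizing single-laboratory
    study populations by animal breeding site improves replicability across
    laboratories. Provides a synthetic multi-laboratory phenotype simulator
    with a crossed random-effects variance model and realistic missingness,
    variance decomposition (MANOVA with Pillai-trace effect sizes and
    mixed models with cage random intercepts), linear discriminant
    classification by breeding site and laboratory, Levene/Brown-Forsythe
    variance-equality contrasts with Fisher-combined probabilities,
    random-effects meta-analysis across laboratories with a
    coverage-probability statistic, and a simulated-sampling power analysis
    based on the first principal component of the outcome battery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    lme4,
    lmerTest,
    metafor
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
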