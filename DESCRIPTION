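Package: thermoscape
Title: Life-Stage Thermal Performance and Dispersal-Constrained Range
    Projections on River Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Couples catchment-scale species distribution model (SDM)
    ensembles with life-stage thermal performance curves (TPCs) to project
    climate-driven range and performance change for riverine ectotherms.
    Provides a seeded synthetic-world generator (dendritic catchment
    networks, monthly water temperatures for a baseline and a warmed
    future, covariates, dams, laboratory trait observations, occurrences),
    trait finalization and Deutsch-type survivorship curves per life stage
    (adult, juvenile, egg), an ensemble of tunable presence-absence
    learners with mean-probability consensus, AUC/TSS validation and
    sensitivity-specificity threshold selection, three dispersal scenarios
    (no, free, restricted by dams) resolved on the river network, and
    monthly/seasonal/annual/spawning-season performance summaries with
    latitudinal profiles and suitability-performance correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    igraph,
    glmnet,
    ranger,
    xgboost,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
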