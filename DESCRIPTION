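Package: chronogut
Title: Social Jetlag, Diet and Gut Microbiome Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives chronobiological sleep metrics (mid-sleep, social
    jetlag, chronotype), chrononutrition features from time-stamped meal
    logs, plant-based diet indices from food-frequency intakes, continuous
    glucose monitoring summaries and postprandial incremental areas under
    the curve from participant-level cohort tables; screens gut microbial
    species for differential relative abundance between social-jetlag
    groups with prevalence filtering, Mann-Whitney tests, Cohen's effect
    sizes and Benjamini-Hochberg false-discovery control; runs
    covariate-adjusted group comparisons, interaction models, partial
    correlations and age matching; and quantifies diet-mediated effects of
    social jetlag on species abundance with mixed-model causal mediation
    and quasi-Bayesian inference. A synthetic-cohort generator with
    planted, recoverable effects makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    MASS,
    ranger,
    emmeans,
    sandwich,
    lmtest,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, StatisticalMethod, Epidemiology
RoxygenNote: 7.3.3
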