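Package: wasa
Title: Weight-Adjusted Standardized Adherence Scoring and Sex-Stratified
    Analysis of Low-Carbohydrate vs Low-Fat Diet Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for sex-stratified secondary analysis of 12-month
    weight-loss trials comparing healthy low-carbohydrate (HLC) and healthy
    low-fat (HLF) diets. Implements the weight-adjusted standardized
    adherence (WASA) score from repeated 24-hour dietary recalls, a
    random-intercept linear mixed model fitted by profiled restricted
    maximum likelihood with Satterthwaite denominator degrees of freedom
    for omnibus and pairwise contrasts of 12-month changes in weight, fat
    mass and lean mass by diet-sex group, adherence regression,
    adherence-outcome Spearman correlations, a descriptive mediation check,
    baseline descriptive tables with Kruskal-Wallis, Dunn-Bonferroni and
    Fisher exact tests, and a seeded synthetic trial-cohort generator that
    emulates the longitudinal structure, dropout and DEXA availability of
    such trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    jsonlite,
    withr
Config/testthat/edition: 3
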