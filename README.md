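# wasa

Sex-stratified analysis of 12-month weight-loss trials comparing a healthy
low-carbohydrate (HLC) with a healthy low-fat (HLF) diet, built around two
pieces of machinery:

* the **weight-adjusted standardized adherence (WASA) score** — from
  up-to-three 24-hour dietary recalls per timepoint, average the arm's
  restricted macronutrient (carbohydrate on HLC, fat on HLF), take the
  deviation from the 20 g/day goal (`20 − mean`), divide by baseline weight
  (the deviation score DS, g/kg), z-score DS within diet × month strata,
  and average the available month-3/6/12 z-scores:

  `WASA_i = mean_t { (DS_it − mean_dt) / sd_dt }`

  so 0 is average adherence relative to the diet's cohort and positive is
  better than average;

* a **random-intercept linear mixed model** for change from baseline, fit by
  profiled REML, with fixed effects for diet-sex group (HLC-F, HLC-M, HLF-F,
  HLF-M), month, their interaction, and the baseline confounders weight and
  body-fat percentage. Omnibus and pairwise tests use **Satterthwaite
  denominator degrees of freedom** (`ν = 2 [c'V_β c]² / (g' Σ_θ g)` via the
  delta method on the REML information).

Around these sit the adherence-by-group regression, Spearman correlations of
WASA with 12-month percent change, a descriptive mediation check
(contrasts with vs without WASA adjustment), Kruskal–Wallis /
Dunn–Bonferroni / Freeman–Halton Fisher descriptive tables, and a seeded
synthetic cohort generator emulating the trial structure (four cells of
179/125/167/138 participants, ~79% month-12 retention, a no-DEXA subset,
and a latent adherence trait linking reported intake to weight change) so
the whole pipeline is testable without access to raw trial data.

The package is for biostatisticians and nutrition-trial methodologists who
want a reusable, tested implementation of this analysis or a simulation
bench for its operating characteristics.

## Worked example

```r
library(wasa)

cohort <- simulate_cohort(cohort_config(seed = 42))
ws  <- wasa_scores(cohort$recalls, cohort$participants)
fit <- fit_lmm(cohort$outcomes, cohort$participants, "weight")
pairwise_contrasts(fit)
#>              label estimate     se    df       t        p  ci_low  ci_high
#>  HLC vs HLF, women  -0.8687 0.3979 989.0 -2.1830   0.0293 -1.6496 -0.08778
#>    HLC vs HLF, men  -2.0293 0.4581 966.3 -4.4295 1.05e-05 -2.9283 -1.13025
#>  men vs women, HLF   0.2021 0.5593 753.8  0.3614   0.7179 -0.8958  1.30009
#>  men vs women, HLC  -0.9585 0.5571 769.8 -1.7206   0.0857 -2.0520  0.13505

omnibus_group_test(fit)
#>          F df1      df2            p
#> 1 8.369865   3 866.7815 1.727299e-05
```

Reading the output: among men this simulated cohort shows 2.03 kg more
12-month weight loss on HLC than HLF (95% CI −2.93 to −1.13, Satterthwaite
df 966), while the women's diet difference is small; the omnibus F rejects
equality of the four adjusted 12-month changes. Estimates vary cohort to
cohort around the generating truth (−2.98 kg for the men's contrast at the
defaults).

```r
adherence_group_regression(ws, cohort$participants)
#> Adherence (WASA) by diet-sex group, n = 602
#>   omnibus F(3, 598) = 6.514, p = 0.0002432
#>              label estimate    se  df     t        p  ci_low ci_high
#>  HLC vs HLF, women   0.0763 0.102 598  0.75 0.453307 -0.1233   0.276
#>    HLC vs HLF, men  -0.0325 0.116 598 -0.28 0.779716 -0.2608   0.196
#>  men vs women, HLF   0.3903 0.109 598  3.59 0.000354  0.1770   0.604
#>  men vs women, HLC   0.2815 0.110 598  2.57 0.010532  0.0661   0.497
```

The positive men-vs-women WASA contrasts here arise even though the
generator's latent adherence is sex-independent: DS divides the same gram
deviation by baseline weight, so heavier participants score as more
adherent. See the methods vignette (`vignettes/wasa-methods.Rmd`) for this
and the other structural properties of the score.

A one-command run — simulate, score, fit all three measures, associate,
describe, and write CSVs plus a markdown report with seed/version/config
metadata — is:

```r
run_pipeline(cohort_config(seed = 42), out_dir = "out")
```

`run_pipeline()` also accepts pre-loaded `participants`/`outcomes`/`recalls`
tables (schemas: `participants.csv` — participant_id, sex, diet,
baseline_weight_kg, baseline_bodyfat_pct; `outcomes.csv` — participant_id,
measure, month, value_kg; `recalls.csv` — participant_id, month, day_index,
carb_g, fat_g, protein_g, energy_kcal).

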