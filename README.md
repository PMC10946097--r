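# dtthiv — phenotyping difficult-to-treat HIV in registry data

`dtthiv` operationalizes **difficult-to-treat HIV** over longitudinal
HIV-registry extracts and analyzes its treatment outcomes. It is written
for epidemiologists and register analysts who need a reproducible,
testable implementation of a multi-rule cohort phenotype — the kind of
definition that is easy to state in a sentence and easy to get subtly
wrong in code.

A person is classified as difficult-to-treat at an index date when at
least one of five categories applies:

| category | rule (at index date *t*) |
|---|---|
| Advanced resistance | intermediate/high-level resistance to ≥ 2 drugs in ≥ 2 drug classes, cumulative over all tests |
| Four-drug regimen | current regimen with ≥ 4 non-booster drugs, after a past 2–3-drug regimen |
| Salvage therapy | current regimen contains IBA/FTR/ENF/MVC/ETR, BID dolutegravir, or boosted BID darunavir |
| Recent virologic failure | two VL ≥ 200 c/mL, ≥ 90 d apart, within (*t* − 365 d, *t*], and ≥ 1826 d cumulative ART |
| ≥ 2 switches following failure | ≥ 2 consecutive regimens each with VL ≥ 50 c/mL on-regimen followed by a switch ≤ 183 d later, from 2008 on |

All regimen logic works on *regimens* derived from per-drug episodes as
maximal half-open intervals of constant drug set. Outcomes (viral
suppression on the last available measurement, dichotomized 1–6 Likert
satisfaction with physical and psychological health) are compared between
difficult and non-difficult persons with crude and adjusted logistic
models: OR = e^β for the difficult indicator, adjusted for sex, linear
current age and transmission risk group, with Wald 95% CIs.

Because real national-register data are confidential, the package includes
a seeded synthetic-registry generator whose defaults mirror the Swedish
cohort structure (n = 8531, category prevalences 0.6–6.1%, 67% resistance
testing, 48% questionnaire coverage) and which *plants* ground-truth
labels by construction — every generated history provably satisfies
exactly its intended flags, so the classifier can be validated to zero
discordance.

## Worked example

```r
library(dtthiv)

cfg   <- scenario_config(n_persons = 2000, seed = 42)
sim   <- generate_cohort(cfg)                       # registry + planted labels
flags <- classify_cohort(sim$registry, cfg$index_date)

mean(flags$difficult)                               # 0.102  (10.2% difficult)
identical(flags$difficult, sim$labels$difficult)    # TRUE   (exact recovery)

outcomes <- derive_outcomes(sim$registry, cfg$index_date)
suppression_by_category(flags, outcomes)
#>         category n_assessed n_suppressed      rate
#> 1: non_difficult       1698         1609 0.9475854
#> 2:     difficult        197          174 0.8832487
#> 3:            AR         44           40 0.9090909
#> 4:           4DR         12            9 0.7500000
#> 5:            ST         35           31 0.8857143
#> 6:        VF12mo         12           10 0.8333333
#> 7:      VFswitch        131          116 0.8854962

models <- fit_outcome_models(flags, outcomes, sim$registry$persons,
                             cfg$index_date)
models[models$outcome == "viral_suppression",
       c("adjusted", "n_analyzed", "odds_ratio", "ci_low", "ci_high")]
#>    adjusted n_analyzed odds_ratio    ci_low   ci_high
#> 1:    FALSE       1895  0.4184614 0.2577999 0.6792473
#> 2:     TRUE       1854  0.4074257 0.2496775 0.6648405
```

The suppression table reads: of 197 assessed difficult-to-treat persons,
174 (88%) had a last viral load < 50 copies/mL against 95% of the
non-difficult group; the crude odds ratio of suppression for difficult vs
non-difficult is 0.42 (95% CI 0.26–0.68), essentially unchanged by
adjustment. At this cohort size a single seed scatters around the
generator's true odds ratio of 0.29.

`venn_counts(flags)` tabulates all 31 category intersections (cells under
10 persons are flagged for display suppression); `table1()` produces the
baseline-characteristics comparison; `run_pipeline()` writes the full
report (flags, tables, Venn cells, sensitivity analysis, JSON manifest)
to a directory. A thin command-line wrapper with `simulate`, `classify`,
`analyze` and `report` subcommands is installed at `inst/cli/dtt.R`.

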