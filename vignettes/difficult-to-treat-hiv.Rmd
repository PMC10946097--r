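---
title: "Phenotyping difficult-to-treat HIV: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping difficult-to-treat HIV: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The phenotype

National HIV registers hold per-drug prescription episodes, viral-load
series, interpreted resistance tests and (sometimes) patient-reported
health items. "Difficult-to-treat HIV" is not a laboratory value but an
operational phenotype over this longitudinal record. `dtthiv` implements a
five-category definition; a person is difficult-to-treat when at least one
category applies at the index date (normally the data-extraction date):

1. **Advanced resistance** — intermediate or high-level interpreted
   resistance (four-level scale: susceptible < low < intermediate < high)
   to at least two antiretrovirals spanning at least two drug classes.
2. **Four-drug regimen (4DR)** — a current regimen of four or more
   non-booster drugs in a person who has been on a two- or three-drug
   regimen in the past.
3. **Salvage therapy** — a current regimen containing ibalizumab,
   fostemsavir, enfuvirtide, maraviroc or etravirine, or twice-daily
   dolutegravir, or twice-daily boosted darunavir — the drug flags alone
   decide, regardless of the indication behind the regimen.
4. **Recent virologic failure** — two viral loads ≥ 200 copies/mL at least
   3 months apart within the past 12 months, in a person with at least
   5 years of cumulative ART exposure.
5. **≥ 2 switches following failure** — at least two *consecutive*
   regimens that each failed (a measurement ≥ 50 copies/mL taken on the
   regimen, followed by a regimen switch within 6 months), counting
   failures on or after 2008-01-01 (the point at which register coverage
   becomes national and regimen histories reliable).

The categories are deliberately non-exclusive; their intersections are a
result in their own right (`venn_counts()`).

## From per-drug episodes to regimens

The register stores exposure one drug at a time. All regimen-level rules
operate on a derived object: a *regimen* is a maximal calendar interval
over which the set of simultaneously active drugs is constant
(`build_regimens()`). The construction is an interval sweep over the
episode breakpoints, with three conventions:

* **Half-open intervals** `[start, end)`. A regimen ending exactly on the
  index date is not current, and the day a switch happens belongs to the
  new regimen only. This makes switch adjacency unambiguous.
* **Gaps are not regimens.** Days covered by no drug separate regimens;
  two identical drug sets on either side of a gap are distinct regimens
  (a configurable tolerance, default 0 days, can bridge short
  administrative gaps).
* **A switch is any change in the drug set.** The register cannot
  distinguish a substitution of a core agent from any other modification,
  so none is attempted.

Cumulative ART duration (`art_duration_days()`) counts days covered by at
least one regimen — exposure time, not time since first start. This is the
stricter reading of "on ART for ≥ 5 years" and the one that cannot be
satisfied by a person who started long ago but spent years off therapy.

Pharmacokinetic boosters (ritonavir-as-booster, cobicistat) are never
counted as drugs. The packaged catalog (`default_drug_catalog()`) flags
them and assigns each drug a class; it is an editable CSV because register
drug coding is site-specific.

## Fixed day equivalents

The category definitions use month and year units. For reproducibility the
classifier uses fixed day equivalents, all exposed in `dtt_thresholds()`:

| parameter | meaning | default |
|---|---|---|
| `min_days_apart` | "at least 3 months apart" | 90 d |
| `recent_window_days` | "within the past 12 months" | 365 d |
| `min_art_days` | "on ART for ≥ 5 years" | 1826 d |
| `switch_within_days` | "switch within 6 months" | 183 d |
| `vf_recent_threshold` | confirming viral load | 200 copies/mL |
| `vf_switch_threshold` | failing viral load for the switch rule | 50 copies/mL |
| `suppression_threshold` | suppression outcome | 50 copies/mL |
| `switch_rule_since` | failures counted from | 2008-01-01 |
| `four_dr_min` | minimum non-booster drugs for 4DR | 4 |
| `art_start_exclusion_days` | "starting ART < 6 months ago" | 183 d |
| `pro_window_days` | questionnaire look-back | 730 d |

All boundaries are inclusive on the side that makes the printed definition
literal: a 90-day spacing, a viral load of exactly 200, exactly 1826 ART
days and a switch at exactly 183 days all satisfy their rules; 89 days,
199 copies, 1825 days and 184 days do not. `generate_adversarial_histories()`
encodes every one of these boundaries with hand-derived expected flags,
and the test suite asserts them.

## Decisions where the definition is open

Several aspects of the phenotype are underdetermined by its one-sentence
definitions. The package resolves them as follows (each is a documented
convention, not a hidden branch):

* **"Currently" means the regimen whose interval contains the index
  date**, not the most recent prescription. A person whose last regimen
  ended before the index date has no current regimen and cannot be 4DR or
  salvage.
* **Resistance is cumulative**: the per-drug maximum level over all tests
  ever recorded. Archived resistance remains clinically relevant, and a
  definition based on the latest test only would flip with every
  susceptible re-test.
* **"Boosted darunavir BID" requires a booster in the same regimen**, not
  a BID booster; dosing flags apply to the drug itself. A missing or
  unknown dosing flag conservatively counts as not-BID.
* **The 2008 anchor applies to the failing measurement**, because the
  measurement is the event that defines the failure; the regimen may have
  started earlier.
* **"Consecutive regimens" are adjacent in the person's regimen
  sequence**; a treatment gap between them does not break adjacency (a
  gap is not a regimen). A viral load measured during a gap belongs to no
  regimen and can fail nothing.
* **People with no viral load can satisfy no failure rule; people with no
  resistance test cannot have advanced resistance.** Nothing is imputed.
* **The 4DR count is ≥ 4** (configurable), since an exactly-4 reading
  would arbitrarily unflag five-drug rescue regimens.

## Treatment outcomes and models

`derive_outcomes()` excludes people whose first-ever ART start is within
183 days of the index date, then defines suppression on the *last
available* measurement — assessed only when some measurement falls in the
last 12 months — as below 50 copies/mL, accepting "< limit" results when
the assay limit is at most 50 (a "< 400" result cannot confirm
suppression). Patient-reported physical and psychological health come from
the most recent questionnaire within 24 months, dichotomized at ≥ 5 on the
1–6 satisfaction scale; item-level missingness is preserved, which is why
the two items have slightly different analyzed n.

`fit_outcome_models()` fits, per outcome, a crude logistic model
(outcome ~ difficult) and an adjusted model adding sex, current age
(linear, centered at 50 years — centering aids numerics and cannot change
odds ratios) and transmission risk group (reference: heterosexual).
Intervals are Wald on the log-odds scale with no small-sample correction
and no multiplicity adjustment. The crude logistic odds ratio is
algebraically the 2×2 odds ratio; the test suite asserts agreement to six
significant digits, and `odds_ratio_2x2()` refuses zero cells rather than
silently continuing (exact or penalized methods are out of scope). Group
comparisons in `table1()` use the Mann-Whitney U test for continuous
variables and Pearson's chi-squared (no continuity correction) for
categorical ones. The Mann-Whitney p-value uses the normal approximation
with tie *and* continuity correction: with the small per-group counts the
test suite checks against exact permutation, the uncorrected approximation
is visibly anticonservative at extreme U, while the corrected one tracks
the exact p within 0.02.

Because the recent-virologic-failure category nearly implies
non-suppression, `sensitivity_excluding_recent_vf()` recomputes the
suppression comparison with that category removed from the analysis.

## The synthetic registry

The full-scale registry behind the phenotype is confidential, so the
package ships a seeded generator (`generate_cohort()`) whose *defaults are
the study conditions*: 8 531 persons classified at 2023-04-06; category
prevalences 2.2% (advanced resistance), 0.6% (4DR), 1.7% (salvage), 0.7%
(recent failure) and 6.1% (repeated switches), taken from the reference
cohort's counts; resistance-testing coverage 67%; questionnaire coverage
48%; suppression probability 95% among non-difficult and the value implied
by a true crude odds ratio of 0.29 (≈ 84.6%) among difficult; physical /
psychological satisfaction 55% / 64% vs 63% / 66%. Overlap between
categories is induced by pairwise enrichment factors fixed from the
printed intersections (about 70% of recent-failure cases also carry the
switch category; P(salvage | advanced resistance) = 45/188), with the
complement conditional solved so each marginal is preserved; an
enrichment that cannot fit inside its marginal raises an error. The
implied union is ≈ 9.5%, and the calibration test checks the mean over
seeds against the configured 9.4% within one percentage point.

Plants are **constructed, not rejection-sampled**: a recent-failure plant
receives two measurements of 250–20 000 copies placed 95–180 days apart
inside the final year on ≥ 2 200 days of uninterrupted ART; a
switch-after-failure plant receives two or three consecutive failing
regimens (failing measurement, then a switch within at most 150 days)
ending more than 450 days before the index date; a 4DR plant gets a
four-non-booster current regimen after a guaranteed two/three-drug past;
salvage plants draw their marker (BID darunavir + booster, etravirine, or
BID dolutegravir) with weights mirroring the reference cohort. Non-plants
violate every rule by an explicit margin: routine measurements are
below-limit results, near-miss constructions place confirming pairs 60
days apart, single failing regimens, identical failure patterns entirely
before 2008, two high-level resistance calls confined to one class, and
boosterless BID darunavir. Missingness is generated explicitly: ~2% recent
ART starters, ~3% without a recent viral load, 52% without a
questionnaire, 33% without resistance tests. Ground-truth labels are
emitted alongside the tables and are never read by the classifier.

What the generator does **not** emulate: assay-limit changes over calendar
time (all routine results use a 20-copy limit), transmission dynamics,
within-host viral kinetics, correlated comorbidity, informative
questionnaire non-response, and era-accurate drug availability (a modern
template may appear in an early-2000s regimen). Passing the
ground-truth-recovery test therefore shows that the classifier implements
its documented conventions exactly — not that those conventions capture
every ambiguity of real register data, where duplicate episodes,
conflicting dates and coarse "< 400" results are common. The loader's
validation and the duplicate-merge path are tested separately on
constructed pathological inputs.

## Problem sizes and numerical checks in the test suite

The suite runs at sizes chosen to make every stochastic check stable:
ground-truth recovery on a 2 000-person cohort (zero discordance
required); oracle equivalence of the two failure rules against literal
all-pairs / adjacent-pairs scans on 1 000 random histories each;
parameter recovery of the suppression odds ratio over 200 replicates of
n = 2 000 (the mean of the crude estimates must fall within ±0.03 of the
true 0.29; the arithmetic mean sits slightly above the truth by Jensen's
inequality, which the band accommodates); and calibration of the
difficult-to-treat prevalence over 12 seeds. Determinism is asserted
byte-for-byte: the generator saves and restores the RNG state, so a
config plus seed always yields identical tables.

## Limitations

The phenotype inherits the register's blind spots: switch *reasons* are
not recorded, so the switches-after-failure category includes switches
made for tolerability shortly after an incidental blip; resistance is
whatever was tested; and patient-reported outcomes cover under half the
cohort with likely non-response bias. The cross-sectional design supports
no causal reading of the outcome comparisons. These are properties of the
definition itself and are intentionally reproduced, not corrected, by
this implementation.
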