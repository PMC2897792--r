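---
title: "Comorbidity measures from claims: mapping rules, models, and the synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comorbidity measures from claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbidikit)
```

## Scope and model

`comorbidikit` evaluates how much three claims-based comorbidity
classifications add to a minimal logistic risk model for inpatient
mortality. For a cohort of index hospitalizations the baseline model is

$$\operatorname{logit} P(\text{death}) = \beta_0 + \beta_1\,\text{age} +
\beta_2\,\text{male} + \beta_3\,\text{aborigine} + \beta_4\,\text{surgery},$$

with age in years, untransformed (no functional form is imposed because
none is standard in this literature), and surgery defined by membership of
the index DRG in a surgical-DRG table. Each comorbidity measure
contributes a block of binary indicators — presence/absence of each
category, never a weighted score, so the three methods are compared on an
equal footing. Model improvement is measured by
$G^2 = 2(\ell_\text{full} - \ell_\text{base})$, and discrimination by the
tie-aware concordance statistic computed from mid-ranks.

Two ascertainment periods are supported. Under `index_only`, evidence is
the index admission's secondary diagnoses. Under `index_plus_prior`, all
diagnosis fields (principal and secondary) of admissions admitted within
the closed 365-day window before the index admission date are added. The
index admission's *principal* diagnosis never contributes to comorbidity
in either period: it is the cohort-defining condition, and counting it
would conflate disease severity with comorbidity.

## The three mappers and their comorbidity-versus-complication rules

All code matching is prefix matching on decimal-free ICD-9-CM codes (a
reference entry `4280` matches `42800`–`42809`), mirroring the `410.x`
convention of the disease definitions. The bundled lists are snapshots
assembled from the published Deyo (1992) and Romano (1993) Charlson
adaptations and the Elixhauser/HCUP category families; every table is a
plain TSV a user can replace.

The methods differ exactly where the field's debate lies:

* **Elixhauser (30 categories).** An index-sourced code is discounted when
  the index DRG belongs to that category's screen set — if the admission
  was grouped under, say, a heart-failure DRG, a heart-failure secondary
  code may be a complication rather than a comorbidity. Prior-sourced
  codes bypass the screen: a condition documented before the index stay
  cannot be its complication. The original screen is defined over a
  specific DRG version that is jurisdiction dependent, so the shipped
  screen table is an explicitly *synthetic* stand-in with the same
  structure (per-category DRG sets); studies using a real grouper should
  substitute their own table.
* **Charlson variants (17 categories each).** The published adaptations
  can treat complication-prone categories as countable only from prior
  admissions. Which categories are so restricted is not enumerated
  consistently across implementations, so `load_method()` defaults to no
  restriction (all categories countable from index secondary diagnoses,
  keeping index-only Charlson models non-degenerate) and offers
  `prior_rule = "complication_prone"` restricting congestive heart
  failure, cerebrovascular disease and myocardial infarction to prior
  evidence — reproducing the behaviour that such categories are "never
  present" without prior information.

Category hierarchies (metastatic cancer suppresses solid tumour /
any malignancy; complicated diabetes suppresses uncomplicated) are applied
after matching, so profiles are internally consistent.

Because prior evidence can only add category hits, the screen applies
only to index-sourced codes, and the prior-only rule only discounts
index-sourced evidence, profiles are monotone in the period:
`index_only` flags are a subset of `index_plus_prior` flags. The test
suite asserts this over randomized cohorts, and checks the full mapper
against a brute-force evaluator that re-derives every (code, category,
rule) decision independently.

## Degenerate columns, G² accounting and the df conventions

Indicator columns with 0% or 100% prevalence in the analytic cohort are
removed before fitting and reported. Two degree-of-freedom conventions
are printed side by side because both occur in applied reports:
`df_diff`, the difference in estimated parameter counts between full and
baseline model, is the statistically correct df for the χ² reference
distribution and is what the p-value uses; `df_total` counts all
non-intercept parameters of the full model, which is what some published
tables print next to G². Reporting both avoids guessing which convention
a reader expects. Aliased (perfectly collinear) columns estimate no
parameter and are excluded from both counts.

## C-statistic and bootstrap

The concordance statistic is computed from mid-ranks,
$c = \big(\sum_{i:\,y_i=1} r_i - n_1(n_1+1)/2\big)/(n_1 n_0)$, which is
exactly the ties-count-one-half pair definition and is invariant under
strictly increasing transforms of the score. Confidence intervals are
percentile bootstrap (2.5th/97.5th of the replicate distribution): the
resampling unit is the patient, resampled with replacement to the
original n, and the model is *refit* inside every replicate so that
model-fitting variability is part of the interval (`refit = FALSE`
rescoring is available). Replicates whose resampled outcome is
single-class are redrawn and counted; more than 10% redraws triggers a
warning, since it means the event rate is too low for this n. Paired
comparisons refit both models on the *same* resampled rows per replicate
and report the fraction of replicates in which one model's c exceeds the
other's.

A scaled Monte-Carlo check in the test suite (60 simulated datasets of
n = 400, 100 replicates each, truth taken from a single n = 100{,}000
draw) verifies the percentile interval attains near-nominal coverage.

## The synthetic-claims generator

The generator emulates the statistical structure the analysis assumes,
not any real claims database:

* demographics from configurable marginals (normal age clamped to 18–110
  years, Bernoulli male/aborigine/surgery);
* independent Bernoulli latent comorbidities per category — the simplest
  structure that exercises every pipeline stage; correlated comorbidity is
  deliberately not a default;
* an index admission in 2002 (principal diagnosis from the configured
  disease family, DRG from a bundled disease-to-DRG table, length of stay
  2 + Poisson(5) days truncated at year end);
* Poisson-distributed prior admissions uniform in the lookback year;
* *coding noise* through a single mechanism, `carryover_prob`: each
  latent condition is coded on each admission independently with this
  probability (default 0.7), into at most 4 secondary slots (random
  subset if more are coded). This is exactly the mechanism that makes
  lookback informative — a condition missed on the index claim may
  surface on a prior claim;
* mortality from a logistic model on baseline covariates and latent
  flags, with age entering in decades centred at the configured mean so
  intercepts are interpretable; one intercept per outcome, and 1-year
  deaths drawn with the conditional probability that makes the marginal
  1-year rate match its target. In-hospital death dates fall inside the
  stay; other first-year deaths are uniform on (discharge, admission+365]
  — only the binary indicator is analysed, so the time distribution is
  immaterial.

Each emission-table category maps to a small set of ICD-9-CM codes with
sampling weights. The code sets are chosen so that shared categories are
visible to all three classifications, a fraction of carriers is coded
with ICD-9-CM codes inside the Romano but not the Deyo families (e.g.
cardiomyopathy-coded heart failure), and several categories exist only in
the Elixhauser classification. This is what gives the shipped
**dominance** scenario its expected rank order
(Elixhauser > Charlson/Romano > Charlson/Deyo): the generating mortality
model loads on Elixhauser-only categories and on Romano-visible codes.
That ordering is therefore a *scenario property* used for qualitative
pattern checks; the package makes no claim that it reproduces any real
cohort's c-statistics.

Scenario defaults: the `ami` and `copd` scenarios use the demographic and
mortality marginals typical of AMI and COPD inpatient cohorts (age
66.31 ± 13.36 vs 72.54 ± 12.10 years; 72% male; in-hospital mortality
14.94% vs 3.02%; 1-year mortality 27.07% vs 22.48%), with intercepts
calibrated by simulation so the generated marginal mortality hits those
targets. Per-category prevalences and coefficient magnitudes are stated
assumptions (no per-category prevalences are published for such cohorts);
they are chosen at plausible claims-study magnitudes and documented in the
YAML scenario files.

What the generator does **not** emulate: correlated comorbidities,
hospital-level coding-depth variation, transfer chains, DRG grouping
logic, seasonality, or competing risks. Tests passing on synthetic data
therefore establish that the *pipeline logic* is correct under the stated
generating model — not that any particular real-data result would
replicate.

## Numerical choices and degenerate inputs

* GLM convergence tolerance is tightened to `epsilon = 1e-10` so that
  log-likelihood differences are stable to well below the `1e-6`
  tolerance used when cross-checking G² against a direct optimizer.
* G² is clipped at 0 with a `1e-6` negativity tolerance; a more negative
  value raises an error (non-nested or non-converged inputs).
* Complete separation is detected heuristically (fitted probabilities at
  the 1e-8 boundary together with a coefficient beyond ±15) and flagged,
  not penalized: the estimator stays plain maximum likelihood.
* Single-class outcomes are errors everywhere (fit, c-statistic) rather
  than NaNs; bootstrap replicates with single-class outcomes are redrawn.
* Deterministic tie-breaks: same-day index candidates prefer the longer
  stay, then the lexicographically smallest principal code; fully
  duplicate admission rows are dropped with a warning.
* Age is completed years at the index admission date; "younger than 18"
  is excluded, so exactly 18 is retained. The 1-year mortality window is
  the closed 365-day interval anchored at the index *admission* date —
  the anchor is a documented choice (`derive_outcomes`), configurable by
  rebuilding outcomes, since conventions differ across studies.

## Problem sizes used by the shipped checks

The test suite runs parameter recovery on 20 generated cohorts of
n = 20,000 (per-coefficient Wald coverage ≥ 90%), rank-order checks on
the dominance scenario at n = 5,000 with 200 bootstrap replications, and
oracle equivalence on thousands of small randomized fixtures. These sizes
were chosen to give the statistical assertions comfortable margins on a
single CPU; all of them are plain parameters of the corresponding test
code and scale up without modification.

## Known limitations

* The bundled code lists are working snapshots, adequate for method
  comparison on synthetic data; a registry-grade study should pin the
  exact list versions for its jurisdiction and period and override the
  TSVs.
* The DRG screen, surgical-DRG and disease-DRG tables are synthetic
  stand-ins (marked by filename); results that depend on screen
  membership should be read as demonstrations of the rule, not of any
  real DRG system.
* No weighted Charlson or van Walraven score, no ICD-10 mappings, no
  calibration statistics or time-to-event models: the evaluation targets
  binary-indicator modelling with G² and c only.
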