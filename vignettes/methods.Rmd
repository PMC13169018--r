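---
title: "Methods: diet-quality scoring, synthetic cohorts, and the association/mediation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet-quality scoring, synthetic cohorts, and the association/mediation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietiq)
```

`dietiq` implements an analysis chain common in prenatal nutritional
epidemiology: a predefined diet-quality score for pregnancy is the
exposure, child brain volumes (cm³) are mediators, child IQ is the
outcome, and inference runs through covariate-adjusted linear models
with false-discovery-rate control, multiple imputation of covariates,
and simulation-based causal mediation. Because individual-level cohort
data of this kind are shareable only under data-use agreements, the
package pairs the analysis code with a synthetic cohort generator that
emulates the statistical structure such data typically show, so every
stage is testable end to end.

## The diet-quality score

The score sums 15 food-component scores, each in $[0,1]$, to a total in
$[0,15]$ (higher = healthier). Components are scored by kind:

* **Adequacy** (vegetables ≥200 g/d, fruit ≥200 g/d, whole grains
  ≥90 g/d, legumes ≥135 g/w, nuts ≥15 g/d, dairy ≥300 g/d, fish
  ≥100 g/w, tea ≥450 g/d): score $=\min(\text{intake}/\text{cut-off},
  1)$. A fruit intake of 120 g/d scores $120/200 = 0.6$.
* **Ratio** (grain quality = whole grains / total grains; soft fats and
  oils as a fraction of total fat): the ratio is the score. An undefined
  ratio (zero denominator) is scored 0 with a warning — unobserved
  quality earns no credit.
* **Moderation** (red meat ≤375 g/w, sugar-containing beverages
  ≤150 g/d, salt ≤6 g/d), reverse-coded so that lower intake scores
  higher. The guideline sources state the reverse coding but not its
  functional form; we use
  $\mathrm{clamp}(2 - \text{intake}/\text{cut-off},\, 0,\, 1)$: full
  credit at or below the recommended maximum, declining linearly to zero
  at twice the maximum. This keeps the ratio-based construction,
  is continuous, and awards exactly 1 when the guideline is met. One
  consequence worth noting: a record with *zero* intake of every food
  scores 3, not 0, because zero red meat/sugary drinks/salt earns full
  moderation credit; the true minimum-scoring diet has moderation
  intakes at or above twice the cut-offs.
* **Alcohol**: none = 1, any = 0. **Folic-acid supplementation**:
  periconceptional = 1, started within the first 10 weeks = 0.5,
  neither = 0.

Weekly-unit components (legumes, fish, red meat) are scored in g/week
without conversion; the unit labels live in the registry
(`default_registry()`, also shipped as
`inst/extdata/diet_registry.json`). Component scores are never rounded;
totals are rounded only for display. Missing components raise an error
naming the component — there is no silent zero-fill.
`score_excluding_component()` supports the leave-one-component-out
sensitivity analysis, returning both the 14-component score and the
excluded component's intake for use as a covariate.

```{r}
rec <- list(vegetables = 250, fruit = 120, whole_grains = 90,
            legumes = 135, nuts = 15, dairy = 300, fish = 100, tea = 450,
            grain_quality_ratio = 0.5, soft_fat_ratio = 0.5,
            red_meat = 300, sugary_beverages = 0, salt = 5,
            alcohol_any = FALSE, folic_acid = "periconceptional")
score_pregnancy_diet(rec)
```

## What the synthetic cohort emulates

`generate_cohort()` draws mother–child dyads from a structural model:

1. A latent socioeconomic factor $U \sim N(0,1)$ drives the categorical
   maternal covariates (education, income, national origin, smoking)
   through thresholded Gaussian scores, plus maternal age, the
   psychopathology GSI (log-normal, hence right-skewed) and, weakly,
   energy intake. Threshold probabilities match the cohort composition
   the generator targets (66% high education, 64% Dutch origin, 12/22/66%
   income bands, 78.5/9.2/12.3% smoking categories).
2. A latent diet propensity $D = q_u U + q_e E + \varepsilon$ (defaults
   $q_u = 0.25$, $q_e = 0.15$) feeds per-component intake distributions:
   log-normal intakes for adequacy/moderation components, probit-Gaussian
   ratios, a logistic alcohol probability, an ordinal folic-acid
   category. Two free parameters — a global healthiness shift $\delta$
   and the shared loading $r$ of $D$ on components — are calibrated by
   `calibrate_intakes()` (seeded alternating bisection on Monte Carlo
   evaluations with common random numbers, $n = 20{,}000$ per
   evaluation) so the *scored* total hits the target mean 7.8 and SD 1.6
   within 0.05 and 0.1. Both objectives are monotone in their parameter,
   which is why bisection converges; calibrations are cached per target.
3. The child diet score at age 8 (0–10 scale, mean 4.5, SD 1.2) is
   generated to correlate 0.29 with the maternal score.
4. Brain volumes at age 10 are built from compartments — cerebral white
   (≈425 cm³), cerebral gray (≈605 cm³), subcortical (≈56 cm³) and a
   cerebellum/brain-stem remainder — each receiving its configured diet
   effect (defaults 1.83, 1.99, 0.16 cm³ per score unit; the remainder
   absorbs the difference to the 4.54 cm³ total-brain effect), a sex
   effect, a socioeconomic gradient, and Gaussian noise (SDs 55, 65,
   5.5, 15 cm³). Total brain is their sum, so the composition invariant
   white + gray + subcortical ≤ total ≤ intracranial holds row-wise by
   construction; age-14 volumes add growth increments with their own
   noise, carrying the diet effect through.
5. IQ at 14 follows a **single-mediator structural truth**:
   $IQ = \beta_0 + c'S + b\,\mathrm{TBV}_{10} + \gamma\,\mathrm{SES} +
   \varepsilon$, with $(c', b)$ solved from the configured total effect
   (0.65 IQ points/unit) and proportion mediated (7.7%):
   $ab = 0.65 \times 0.077$, $b = ab / 4.54$, $c' = 0.65 - ab$. The
   other volumes mediate only through their correlation with total
   brain, which reproduces the 6–8% range without four free
   $b$-parameters. Subtest t-scores (integer 1–19) give vocabulary and
   matrix reasoning diet effects (0.14, 0.16 per unit) and digit
   span/coding none. The residual IQ SD is 13 points, matching the
   ≈13.5 observed SD of full-scale IQ in such cohorts.

A deliberate design choice: the socioeconomic gradient on volumes and
IQ enters through a fixed linear index of the **observed** model-1
covariate columns (education, income, origin, smoking, GSI, maternal
age), not through the raw latent $U$. The latent factor still induces
confounding — it correlates the diet score with the covariates, so the
crude diet→IQ coefficient is biased upward — but because the outcome's
socioeconomic term lies in the covariate span, model-1 adjustment
identifies the configured effects exactly. Had $U$ entered outcomes
directly, its coarse categorical proxies would leave residual
confounding and no covariate set could recover the configured
parameters, defeating the generator's purpose as a recovery benchmark.

What the generator does **not** emulate: selection/non-response,
measurement error in the FFQ, non-linear dose-response, exposure–
mediator interaction, and longitudinal within-child correlation beyond
the simple growth increments. Passing recovery tests on this cohort
shows the *estimators* are correct under the assumed structure; it says
nothing about those threats to validity in real data.

Baseline volume intercepts are free defaults (no baseline volumes are
printed in the literature the defaults target); they shift means, not
coefficients. Outcome noise SDs are likewise defaults, so CI widths are
not reproduction targets, only coefficient recovery and coverage.

## Missing data

`inject_missingness()` creates missing covariate cells with
probabilities logistic in always-observed variables (maternal age,
child sex) — missing at random, confined to covariates (default rates
5–25% across education, income, smoking, GSI, child diet score,
breastfeeding, serum folate; the intercept of each logistic is solved
so the marginal rate matches the target). Exposure inputs, mediators
and outcomes are never made missing, matching the scope of the
imputation downstream.

`impute_chained()` is a chained-equations imputer: per sweep, each
incomplete covariate is regressed on the others (plus, congenially, the
exposure score, total brain volume and IQ). Continuous covariates use
Bayesian linear-regression draws — $\sigma^2$ from the scaled inverse
chi-square posterior, $\beta$ from its conditional normal, then a
residual draw — not predictive-mean matching, which is simpler to test
and adequate for MAR covariates. Categorical covariates use a
multinomial-logistic model fitted on a bootstrap resample of the
complete cases (the bootstrap supplies parameter uncertainty), with an
observed-frequency fallback if the model fails. Defaults are m = 10
chains of 50 sweeps. `pool_rubin()` combines per-imputation estimates:
$T = W + (1 + 1/m)B$ with Barnard–Rubin small-sample degrees of
freedom when a complete-data df is supplied.

## Association models

`model_spec()` encodes the two covariate sets: model 1 = child sex and
age at imaging, household income, maternal age, education, national
origin, smoking, GSI, energy intake; model 2 adds the child diet score.
Reference levels are the majority categories (income >2200 €/mo, never
smoked, Dutch origin, high education); these affect covariate
coefficients only, never the exposure coefficient. Energy enters as a
covariate (standard multivariable energy adjustment), not by the
residual method. Fits are OLS (`stats::lm`); p-values use the t
distribution with residual df, which matters only at tiny n.

`run_family()` fits the volume family (4 volumes × 2 ages = 8 tests) or
the IQ family (full-scale IQ + 4 subtests = 5 tests) and applies
Benjamini–Hochberg step-up adjustment within the family at FDR 0.05
(`stats::p.adjust`, cross-checked in the tests against a brute-force
"largest $k$ with $p_{(k)} \le k\alpha/m$" oracle). Given an imputation
set it fits per imputation, pools by Rubin's rules, and applies BH to
the pooled p-values. Sensitivity variants: `run_stratified()` (e.g. by
national origin, stratifier dropped from covariates) and
`run_component_exclusion()` (14-component score as exposure, excluded
component's intake as covariate; a zero-variance excluded component is
dropped from the design rather than left to break the fit).

## Causal mediation

`mediate_quasi_bayes()` fits the linear mediator model
$M = \alpha_1 + aS + \theta_1'C$ and outcome model
$Y = \alpha_2 + c'S + bM + \theta_2'C$ and draws `n_sims` (default
1000) coefficient vectors from the normal approximation to each model's
sampling distribution, the two models drawn independently — an
approximation, since both are fit on the same data, but the standard
one for this algorithm family. Per draw, ACME $= ab$, ADE $= c'$, total
$= ab + c'$, so ACME + ADE = total holds exactly per draw and the point
estimates agree with the analytic product-of-coefficients method up to
Monte Carlo error (asserted within 3 MC SEs in the tests). CIs are
percentile 2.5/97.5 across draws.

Numerical choices for the proportion mediated: the point estimate is
the **ratio of point estimates** ACME/total, not the mean of per-draw
ratios — a per-draw ratio has no finite mean when the total-effect
draws cross zero — while the CI does come from the per-draw ratio
percentiles. When the total-effect CI crosses zero the result carries
an `unstable_denominator` flag and a warning. Point summaries of the
effect draws themselves can be means (default) or medians.

`mediate_pooled()` runs the analysis per completed dataset and pools by
concatenating the $m \times$ `n_sims` draws before summarising — a
mixture-of-posteriors combination under which percentile CIs remain
valid; with no missing cells it reduces exactly to the single-table
analysis. Exposure–mediator interaction and sensitivity analysis for
sequential ignorability are out of scope.

## Pipeline and reproducibility

`run_pipeline()` chains generate → score → inject/impute → associate →
mediate, deriving every stage seed deterministically from one global
seed and stamping an MD5 hash of the configuration (minus the output
directory) into every artifact; two runs with the same seed produce
byte-identical tables. `describe_cohort()` reports mean (SD) for
continuous variables, switching to median (IQR) when |skewness| > 1 (a
criterion we fixed ourselves; the convention is standard but the
threshold rarely stated), and percentages for categorical variables. A
thin command-line dispatcher (`inst/exec/dietiq`) exposes `generate`,
`score`, `impute`, `associate`, `mediate` and `run-all` over CSV/JSON
files for shell use.

## Problem sizes used in the test suite

Simulation-based checks run at sizes chosen to balance Monte Carlo
error against runtime: calibration and correlation checks at
n = 100,000 (single cohort); coefficient and mediation recovery at 100
replicates of n = 2223 with 1000 quasi-Bayesian draws; the global-null
FDR simulation at 500 replicates of n = 250; the MAR
imputation-coverage check at 12 replicates of n = 900 with m = 3 chains
of 3 sweeps (a scaled-down version of the full coverage study, with the
acceptance threshold widened accordingly to 9/12). Replicate means at
these sizes have standard errors an order of magnitude below the
tolerances they are checked against.

## Known limitations

* The reverse-coding rule for moderation components is one defensible
  reading of "reversely coded"; guideline-specific scoring may differ
  in the decline rate beyond the cut-off.
* The tea cut-off is treated as grams of brewed beverage; salt intake
  is consumed as a provided column (how it would be estimated from an
  FFQ is instrument-specific).
* Quasi-Bayesian draws treat mediator and outcome models as
  independent; a joint draw would need the cross-model coefficient
  covariance, which OLS theory does not supply without bootstrapping.
* The imputer supports linear/multinomial column models only — no
  interactions, passive imputation, or per-column custom methods.
* The proportion mediated is reported unwinsorised; with weak total
  effects its CI can be extremely wide, which the instability flag
  makes explicit rather than hiding.
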