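# dietiq

Tools for a question nutritional epidemiologists keep returning to: does
maternal diet quality during pregnancy relate to the child's brain
development and cognition years later — and if so, how much of the
cognitive association runs through brain structure?

`dietiq` packages the full analysis chain for studies of this design:

* **Diet-quality scoring** — a predefined 15-component score of
  adherence to Dutch dietary guidelines for pregnancy (range 0–15).
  Adequacy components (vegetables ≥200 g/d, fruit ≥200 g/d, whole grains
  ≥90 g/d, legumes ≥135 g/w, nuts ≥15 g/d, dairy ≥300 g/d, fish
  ≥100 g/w, tea ≥450 g/d) score min(intake/cut-off, 1); two dietary
  ratios (grain quality, soft fats and oils) score as the ratio itself;
  moderation components (red meat ≤375 g/w, sugar-containing beverages
  ≤150 g/d, salt ≤6 g/d) are reverse-coded as clamp(2 − intake/cut-off,
  0, 1); alcohol scores 1 for none / 0 for any; folic-acid supplement
  use scores 1 / 0.5 / 0 for periconceptional / first-10-weeks / no use.
* **Synthetic cohorts** — `generate_cohort()` draws mother–child dyads
  with a latent socioeconomic confounder, calibrated component intakes
  (score mean 7.8, SD 1.6), brain-volume mediators (diet effect
  4.54 cm³/unit on total brain) and IQ outcomes (total effect
  0.65 points/unit, 7.7% mediated through total brain volume), so every
  estimator can be validated by parameter recovery without access to
  restricted cohort data.
* **Association models** — OLS with the study's two covariate sets
  (model 1: sex, age at imaging, income, maternal age, education,
  origin, smoking, psychopathology, energy; model 2: + child diet
  score), Benjamini–Hochberg FDR within the 8-test volume family and
  5-test IQ family, stratified and leave-one-component-out variants.
* **Missing data** — chained-equation multiple imputation of covariates
  (Bayesian regression draws, bootstrap multinomial models) and Rubin's
  rules pooling.
* **Causal mediation** — quasi-Bayesian Monte Carlo decomposition into
  ACME (= a·b), ADE (= c′) and total effect with percentile CIs, singly
  or pooled over imputations.

## Worked example

Score one pregnancy diet record:

```r
library(dietiq)
rec <- list(vegetables = 250, fruit = 120, whole_grains = 90,
            legumes = 135, nuts = 15, dairy = 300, fish = 100, tea = 450,
            grain_quality_ratio = 0.5, soft_fat_ratio = 0.5,
            red_meat = 300, sugary_beverages = 0, salt = 5,
            alcohol_any = FALSE, folic_acid = "periconceptional")
score_pregnancy_diet(rec)
#> Pregnancy diet-quality score: 13.6 of 15
#>          vegetables               fruit        whole_grains             legumes
#>                 1.0                 0.6                 1.0                 1.0
#> ...
```

Fruit scores 120/200 = 0.6; every other component meets its guideline
except the two 0.5 ratios, giving a 13.6 total.

Generate a cohort, fit the volume family, decompose the IQ effect:

```r
tab <- generate_cohort(cohort_config(n_dyads = 2223, seed = 7))
run_family(tab, "volumes", model = 1)
#>   outcome     B  ci_low ci_high        p        q significant
#> 1  tbv_10 5.336  3.0550   7.616 4.73e-06 2.25e-05        TRUE
#> 2   wm_10 1.678  0.2217   3.134 2.39e-02 3.39e-02        TRUE
#> 3   gm_10 2.829  1.1453   4.513 9.99e-04 2.00e-03        TRUE
#> 4  sub_10 0.120 -0.0271   0.267 1.10e-01 1.10e-01       FALSE
#> ...

mediate_quasi_bayes(mediation_spec(mediator = "tbv_10", n_sims = 1000,
                                   seed = 7), tab)
#> Quasi-Bayesian mediation (1000 draws)
#>   ACME                   0.0671  (0.0300, 0.1160)
#>   ADE                    0.6904  (0.3590, 1.0350)
#>   Total effect           0.7575  (0.4349, 1.1023)
#>   Prop. mediated         0.0886  (0.0367, 0.1930)
```

`B` is the outcome difference per 1-unit higher diet score (cm³ for
volumes, IQ points for cognition); `q` is the BH-adjusted p-value within
the 8-test family. In this replicate the diet–total-brain coefficient is
5.34 cm³/unit (generative truth: 4.54 — single-replicate sampling error;
averaging replicates recovers the truth) and 8.9% of the diet–IQ effect
runs through total brain volume.

`run_pipeline(pipeline_config(...))` chains all stages — generation,
missingness, imputation, both model families with FDR flags, four
mediation decompositions — deterministically from one global seed, and
`inst/exec/dietiq` exposes the same stages as shell subcommands.

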