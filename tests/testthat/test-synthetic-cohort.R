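test_that("generation is deterministic given the seed", {
  cfg <- cohort_config(n_dyads = 50, seed = 1)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cohort_config(n_dyads = 50, seed = 2)
  expect_false(identical(generate_cohort(cfg)$diet_score,
                         generate_cohort(cfg2)$diet_score))
})

test_that("volume composition and t-score range invariants hold row-wise", {
  tab <- small_cohort(n = 2000, seed = 3)
  for (age in c("10", "14")) {
    g <- function(p) tab[[paste0(p, "_", age)]]
    expect_true(all(g("wm") + g("gm") + g("sub") <= g("tbv") + 1e-9))
    expect_true(all(g("tbv") <= g("icv")))
    expect_true(all(g("icv") > 0))
  }
  for (col in c("vocab_14", "matrix_14", "digit_14", "coding_14")) {
    expect_true(all(tab[[col]] >= 1 & tab[[col]] <= 19))
    expect_true(all(tab[[col]] == round(tab[[col]])))
  }
})

test_that("calibrated intake distributions reproduce the score targets", {
  cal <- calibrate_intakes(7.8, 1.6)
  expect_lt(abs(cal$achieved_mean - 7.8), 0.05)
  expect_lt(abs(cal$achieved_sd - 1.6), 0.1)
  tab <- small_cohort(n = 30000, seed = 5)
  expect_lt(abs(mean(tab$diet_score) - 7.8), 0.08)
  expect_lt(abs(sd(tab$diet_score) - 1.6), 0.12)
  expect_lt(abs(cor(tab$diet_score, tab$child_diet_score) - 0.29), 0.03)
})

test_that("degenerate score targets produce boundary cohorts", {
  hi <- generate_cohort(cohort_config(n_dyads = 20, seed = 1,
                                      score_mean = 15, score_sd = 0))
  expect_equal(hi$diet_score, rep(15, 20))
  lo <- generate_cohort(cohort_config(n_dyads = 20, seed = 1,
                                      score_mean = 0, score_sd = 0))
  expect_equal(lo$diet_score, rep(0, 20))
  expect_true(all(lo$alcohol_any))
  expect_error(calibrate_intakes(7, 0), "boundary")
})

test_that("a null total-brain path yields a zero generative ACME, and infeasible configs error", {
  ev0 <- c(total_brain = 0, cerebral_white = 0, cerebral_gray = 0,
           subcortical = 0)
  tab <- generate_cohort(cohort_config(n_dyads = 30, seed = 2,
                                       effect_volume = ev0,
                                       proportion_mediated_total_brain = 0))
  expect_equal(attr(tab, "truth")$acme, 0)
  expect_equal(attr(tab, "truth")$effect_tbv_on_iq, 0)
  expect_error(cohort_config(effect_volume = ev0,
                             proportion_mediated_total_brain = 0.1),
               "non-zero total-brain effect")
  expect_error(cohort_config(proportion_mediated_total_brain = 1.3))
})

test_that("missingness injection hits the target rates, only in covariates, deterministically", {
  cfg <- cohort_config(n_dyads = 10000, seed = 7)
  tab <- generate_cohort(cfg)
  expect_identical(inject_missingness(tab, cohort_config(n_dyads = 10000,
                                                         missingness = c(gsi = 0))),
                   tab)
  mis <- inject_missingness(tab, cfg, seed = 99)
  expect_identical(mis, inject_missingness(tab, cfg, seed = 99))
  for (col in names(cfg$missingness))
    expect_lt(abs(mean(is.na(mis[[col]])) - cfg$missingness[[col]]), 0.02)
  for (col in c("diet_score", "tbv_10", "tbv_14", "iq_14", "vocab_14",
                "vegetables", "alcohol_any", "maternal_age", "child_sex"))
    expect_false(anyNA(mis[[col]]))
  expect_error(inject_missingness(tab, cohort_config(missingness = c(iq_14 = 0.1))),
               "not allowed")
})

test_that("socioeconomic confounding inflates the crude diet-IQ coefficient", {
  crude <- adj <- numeric(10)
  for (i in 1:10) {
    tab <- generate_cohort(cohort_config(n_dyads = 2000, seed = 100 + i))
    crude[i] <- coef(lm(iq_14 ~ diet_score, tab))[["diet_score"]]
    adj[i] <- fit_linear(model_spec("iq_14"), tab)$B
  }
  expect_gt(mean(crude), mean(adj))
  # and with confounding switched off the crude fit is unbiased
  crude0 <- sapply(1:10, function(i) {
    tab <- generate_cohort(cohort_config(n_dyads = 2000, seed = 200 + i,
                                         confounding_strength = 0))
    coef(lm(iq_14 ~ diet_score, tab))[["diet_score"]]
  })
  expect_lt(abs(mean(crude0) - 0.65), 0.15)
})
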