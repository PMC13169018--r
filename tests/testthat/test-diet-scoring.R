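test_that("adequacy components score the intake/cut-off ratio truncated at 1", {
  expect_equal(score_adequacy_component(120, 200), 0.6)
  expect_equal(score_adequacy_component(0, 200), 0)
  expect_equal(score_adequacy_component(450, 200), 1)
  expect_equal(score_adequacy_component(c(50, 200, 900), 200),
               c(0.25, 1, 1))
  expect_error(score_adequacy_component(-1, 200), "non-negative")
  expect_error(score_adequacy_component(10, 0), "positive")
})

test_that("moderation components reverse-code linearly between 1x and 2x the cut-off", {
  expect_equal(score_moderation_component(375, 375), 1)
  expect_equal(score_moderation_component(750, 375), 0)
  expect_equal(score_moderation_component(0, 150), 1)
  expect_equal(score_moderation_component(562.5, 375), 0.5)
  expect_error(score_moderation_component(-5, 375), "non-negative")
})

test_that("ratio components score the ratio itself; undefined ratios score 0 with a warning", {
  expect_equal(score_ratio_component(c(0, 0.5, 1)), c(0, 0.5, 1))
  expect_warning(s <- score_ratio_component(NA), "undefined ratio")
  expect_equal(s, 0)
  expect_error(score_ratio_component(1.2), "\\[0, 1\\]")
})

test_that("alcohol and folic-acid components follow the categorical rules", {
  expect_equal(score_alcohol(FALSE), 1)
  expect_equal(score_alcohol(TRUE), 0)
  for (x in c(TRUE, FALSE))
    expect_equal(score_alcohol(x) + score_alcohol(!x), 1)
  expect_equal(score_folic_acid("periconceptional"), 1)
  expect_equal(score_folic_acid("first_10_weeks"), 0.5)
  expect_equal(score_folic_acid("none"), 0)
  expect_error(score_folic_acid("sometimes"), "unknown folic-acid category")
  expect_error(score_alcohol(NA), "TRUE/FALSE")
})

test_that("the total score sums the 15 component scores", {
  expect_equal(score_pregnancy_diet(max_record())$total, 15)
  expect_equal(score_pregnancy_diet(min_record())$total, 0)
  s <- score_pregnancy_diet(half_record())
  expect_equal(s$total, 9.6)  # hand-summed component-by-component
  expect_equal(unname(s$component_scores[["fruit"]]), 0.6)
  expect_equal(s$total, sum(s$component_scores), tolerance = 1e-9)
})

test_that("a missing component is an error naming the component, never a zero-fill", {
  rec <- half_record()
  rec$fish <- NULL
  expect_error(score_pregnancy_diet(rec), "fish")
  rec2 <- half_record()
  rec2$folic_acid <- NULL
  expect_error(score_pregnancy_diet(rec2), "folic_acid")
})

test_that("leave-one-component-out scores obey the additivity identity", {
  expect_equal(score_excluding_component(max_record(),
                                         excluded = "fruit")$score$total, 14)
  loo <- score_excluding_component(half_record(), excluded = "folic_acid")
  expect_equal(loo$score$total, 9.1)
  expect_error(score_excluding_component(half_record(), excluded = "pizza"),
               "unknown component")
  full <- score_pregnancy_diet(half_record())
  for (comp in default_registry()$name) {
    loo <- score_excluding_component(half_record(), excluded = comp)
    expect_equal(loo$score$total + full$component_scores[[comp]], full$total,
                 tolerance = 1e-12)
  }
})

test_that("component scores stay in [0,1] and totals in [0,15] for arbitrary records", {
  set.seed(404)
  for (i in 1:50) {
    s <- score_pregnancy_diet(random_record())
    expect_true(all(s$component_scores >= 0 & s$component_scores <= 1))
    expect_gte(s$total, 0)
    expect_lte(s$total, 15)
  }
})

test_that("adequacy scores are non-decreasing and moderation scores non-increasing in intake", {
  grid <- sort(runif(30, 0, 900))
  expect_true(all(diff(score_adequacy_component(grid, 200)) >= 0))
  expect_true(all(diff(score_moderation_component(grid, 375)) <= 0))
})

test_that("table scoring matches record-at-a-time scoring and validates columns", {
  tab <- as.data.frame(rbind(as.data.frame(half_record()),
                             as.data.frame(max_record()),
                             as.data.frame(min_record())))
  scored <- score_intake_table(tab)
  expect_equal(scored$diet_score, c(9.6, 15, 0))
  expect_error(score_intake_table(tab[setdiff(names(tab), "tea")]), "tea")
})

test_that("the shipped JSON registry matches the built-in default", {
  path <- system.file("extdata", "diet_registry.json", package = "dietiq")
  reg <- read_registry(path)
  expect_equal(reg$name, default_registry()$name)
  expect_equal(reg$cutoff, default_registry()$cutoff)
  expect_equal(nrow(reg), 15)
})

test_that("the score correlates positively with the fiber proxy and negatively with saturated fat", {
  tab <- small_cohort(n = 3000, seed = 11)
  expect_gt(cor(tab$diet_score, tab$fiber_proxy), 0)
  expect_lt(cor(tab$diet_score, tab$satfat_proxy), 0)
})
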