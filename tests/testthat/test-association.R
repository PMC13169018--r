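test_that("a noiseless line is fitted exactly", {
  tab <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
  fit <- suppressWarnings(fit_linear(bare_spec("y", "x"), tab))
  expect_equal(fit$B, 2)
  expect_equal(fit$se, 0)
  expect_equal(fit$p, 0)
})

test_that("the three-point slope matches the hand normal-equations value", {
  tab <- data.frame(x = c(0, 1, 2), y = c(0, 1, 3))
  fit <- fit_linear(bare_spec("y", "x"), tab)
  expect_equal(fit$B, 1.5)
  expect_equal(unname(coef(lm(y ~ x, tab))[1]), -1 / 6)
  expect_true(fit$ci_low <= fit$B && fit$B <= fit$ci_high)
})

test_that("OLS agrees with the brute-force normal-equations oracle", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(8:50, 1); p <- sample(1:5, 1)
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("v", seq_len(p))
    tab <- as.data.frame(X)
    tab$y <- rnorm(n, X %*% runif(p, -2, 2), 1)
    fit <- fit_linear(bare_spec("y", "v1",
                                covariates = setdiff(colnames(X), "v1")), tab)
    orc <- ols_oracle(cbind(1, X), tab$y)
    expect_equal(fit$B, orc$beta[[2]], tolerance = 1e-10)
    expect_equal(fit$se, orc$se[[2]], tolerance = 1e-10)
  }
})

test_that("rank-deficient designs and missing cells are rejected", {
  tab <- data.frame(x = 1:10, x2 = 2 * (1:10), y = rnorm(10))
  expect_error(fit_linear(bare_spec("y", "x", "x2"), tab), "collinear")
  tab2 <- data.frame(x = 1:10, y = rnorm(10))
  tab2$y[3] <- NA
  expect_error(fit_linear(bare_spec("y", "x"), tab2), "missing cells")
  expect_error(fit_linear(bare_spec("y", "x"), data.frame(x = 1:3)), "lacks")
})

test_that("Benjamini-Hochberg adjustment matches hand and brute-force oracles", {
  adj <- bh_adjust(c(0.005, 0.04, 0.03))
  expect_equal(adj$q, c(0.015, 0.04, 0.04))
  expect_equal(bh_adjust(rep(0, 4))$q, rep(0, 4))
  expect_equal(bh_adjust(0.037)$q, 0.037)
  expect_identical(bh_adjust(numeric(0))$q, numeric(0))
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:30) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)
    adj <- bh_adjust(p, fdr = 0.05)
    expect_identical(adj$significant, bh_oracle_reject(p, 0.05))
    expect_true(all(adj$q >= p - 1e-12))
    expect_true(all(adj$q <= 1))
  }
})

test_that("outcome families have the right cardinality and valid inference fields", {
  tab <- small_cohort(n = 600, seed = 8)
  vol <- run_family(tab, "volumes")
  iq <- run_family(tab, "iq")
  expect_equal(nrow(vol), 8)
  expect_equal(nrow(iq), 5)
  for (res in list(vol, iq)) {
    expect_true(all(res$q >= res$p - 1e-12))
    expect_true(all(res$q >= 0 & res$q <= 1))
    expect_true(all(res$ci_low <= res$B & res$B <= res$ci_high))
    expect_equal(res$n, rep(nrow(tab), nrow(res)))
  }
})

test_that("run_family pools per-imputation fits before the BH step", {
  cfg <- cohort_config(n_dyads = 500, seed = 15,
                       missingness = c(gsi = 0.2))
  mis <- inject_missingness(generate_cohort(cfg), cfg)
  imp <- impute_chained(mis, m = 3, iterations = 2, seed = 3)
  res <- run_family(imp, "iq")
  expect_equal(nrow(res), 5)
  expect_true(all(is.finite(res$se)))
  # pooled estimate equals the mean of the per-imputation fits
  fits <- vapply(imp$completed,
                 function(d) fit_linear(model_spec("iq_14"), d)$B, 0)
  expect_equal(res$B[res$outcome == "iq_14"], mean(fits))
})

test_that("adjusting for child diet attenuates the maternal diet coefficient on average", {
  b1 <- b2 <- numeric(15)
  for (i in 1:15) {
    tab <- generate_cohort(cohort_config(n_dyads = 1500, seed = 300 + i))
    b1[i] <- fit_linear(model_spec("iq_14", model = 1), tab)$B
    b2[i] <- fit_linear(model_spec("iq_14", model = 2), tab)$B
  }
  expect_lt(mean(abs(b2)), mean(abs(b1)))
})

test_that("leave-one-component-out analyses return one stable fit per component", {
  tab <- small_cohort(n = 800, seed = 12)
  res <- run_component_exclusion(tab)
  expect_equal(nrow(res), 15)
  expect_setequal(res$excluded, default_registry()$name)
  expect_true(all(res$B > 0))  # no exclusion flips the positive diet effect
  # a zero-variance excluded component leaves the exposure fit unchanged
  tab0 <- tab
  tab0$salt <- 6
  res0 <- run_component_exclusion(tab0)
  base <- score_intake_table(tab0)
  tab0$diet_score_loo <- base$diet_score - base$score_salt
  ref <- fit_linear(model_spec("tbv_10", exposure = "diet_score_loo"), tab0)
  expect_equal(res0$B[res0$excluded == "salt"], ref$B, tolerance = 1e-10)
})

test_that("stratified fits partition the sample and drop the stratifier", {
  tab <- small_cohort(n = 1000, seed = 14)
  res <- run_stratified(tab, "tbv_10", "origin")
  expect_equal(nrow(res), 2)
  expect_equal(sum(res$n), nrow(tab))
  expect_false(any(grepl("origin", names(coef(lm(
    reformulate(c("diet_score", model_spec("tbv_10",
      stratum = list(column = "origin", level = "dutch"))$covariates),
      "tbv_10"), tab))))))
  one <- tab[tab$origin == "dutch", ]
  expect_error(run_stratified(one, "tbv_10", "origin"), "single level")
})
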