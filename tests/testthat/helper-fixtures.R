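# Fixtures built in code: worked intake records and bare model specs for
# oracle tests that bypass the cohort covariate sets.

# record scoring 0.5 on nine graded components and 0.6 on fruit
# (120/200), 1 on the three at-cut-off moderation components and on
# alcohol, 0.5 on folic acid: hand-summed total
# 0.5 * 9 + 0.6 + 1 * 3 + 1 + 0.5 = 9.6
half_record <- function() {
  list(vegetables = 100, fruit = 120, whole_grains = 45, legumes = 67.5,
       nuts = 7.5, dairy = 150, fish = 50, tea = 225,
       grain_quality_ratio = 0.5, soft_fat_ratio = 0.5,
       red_meat = 375, sugary_beverages = 150, salt = 6,
       alcohol_any = FALSE, folic_acid = "first_10_weeks")
}

max_record <- function() {
  list(vegetables = 300, fruit = 450, whole_grains = 90, legumes = 135,
       nuts = 20, dairy = 400, fish = 100, tea = 500,
       grain_quality_ratio = 1, soft_fat_ratio = 1,
       red_meat = 100, sugary_beverages = 0, salt = 3,
       alcohol_any = FALSE, folic_acid = "periconceptional")
}

min_record <- function() {
  list(vegetables = 0, fruit = 0, whole_grains = 0, legumes = 0, nuts = 0,
       dairy = 0, fish = 0, tea = 0, grain_quality_ratio = 0,
       soft_fat_ratio = 0, red_meat = 1000, sugary_beverages = 500,
       salt = 20, alcohol_any = TRUE, folic_acid = "none")
}

# random non-negative intake record for property tests
random_record <- function() {
  reg <- default_registry()
  rec <- list()
  for (i in seq_len(nrow(reg))) {
    nm <- reg$name[i]
    rec[[nm]] <- switch(reg$kind[i],
      adequacy = , moderation = stats::runif(1, 0, 3 * reg$cutoff[i]),
      ratio = stats::runif(1),
      binary = NULL, categorical = NULL)
  }
  rec$alcohol_any <- stats::runif(1) < 0.5
  rec$folic_acid <- sample(c("periconceptional", "first_10_weeks", "none"), 1)
  rec
}

# model/mediation specs with an arbitrary covariate set, for oracle tests
# on hand-built data frames
bare_spec <- function(outcome, exposure, covariates = character()) {
  structure(list(outcome = outcome, exposure = exposure, model = 1,
                 covariates = covariates, stratum = NULL),
            class = "model_spec")
}

bare_mediation_spec <- function(mediator, outcome, exposure,
                                covariates = character(),
                                n_sims = 1000, seed = 1L) {
  structure(list(mediator = mediator, outcome = outcome, exposure = exposure,
                 covariates = covariates, n_sims = n_sims, seed = seed,
                 point = "mean"),
            class = "mediation_spec")
}

small_cohort <- function(n = 500, seed = 1L, ...) {
  generate_cohort(cohort_config(n_dyads = n, seed = seed, ...))
}

# brute-force OLS oracle via the normal equations
ols_oracle <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  list(beta = drop(beta), se = sqrt(diag(sigma2 * xtx_inv)), df = df)
}

# brute-force BH step-up rejection oracle: largest k with p_(k) <= k a/m
bh_oracle_reject <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- max(c(0, which(ps <= seq_len(m) * alpha / m)))
  rej <- rep(FALSE, m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}
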