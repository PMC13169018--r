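# Covariate-adjusted linear models for diet score -> brain volume / IQ,
# with Benjamini-Hochberg FDR control within the two outcome families.

model1_covariates <- function(age_col) {
  c("child_sex", age_col, "income", "maternal_age", "education",
    "origin", "smoking", "gsi", "energy_kcal")
}

# outcome column -> matching age-at-imaging covariate
age_col_for <- function(outcome) {
  if (grepl("_14$", outcome)) "child_age_14" else "child_age_10"
}

#' Specify an exposure-outcome regression model
#'
#' Model 1 (the main model) adjusts for child sex and age at the imaging
#' assessment, household income, maternal age, education, national
#' origin, smoking during pregnancy, maternal psychopathology (GSI) and
#' energy intake. Model 2 additionally adjusts for the child's own diet
#' score at age 8.
#'
#' @param outcome outcome column name (e.g. \code{"tbv_10"},
#'   \code{"iq_14"}).
#' @param model 1 or 2.
#' @param exposure exposure column (default the maternal diet score).
#' @param extras extra covariate columns (breastfeeding, intracranial
#'   volume, maternal folate, an excluded component's intake, ...).
#' @param stratum optional named list \code{list(column =, level =)}
#'   restricting the fit to one stratum; the stratifier is dropped from
#'   the covariates.
#' @return A list of class \code{"model_spec"}.
#' @export
model_spec <- function(outcome, model = 1, exposure = "diet_score",
                       extras = character(), stratum = NULL) {
  stopifnot(model %in% c(1, 2))
  covs <- model1_covariates(age_col_for(outcome))
  if (model == 2) covs <- c(covs, "child_diet_score")
  covs <- unique(c(covs, extras))
  if (!is.null(stratum)) covs <- setdiff(covs, stratum$column)
  if (exposure %in% covs) stop("exposure may not appear among the covariates")
  structure(list(outcome = outcome, exposure = exposure, model = model,
                 covariates = covs, stratum = stratum),
            class = "model_spec")
}

#' Fit a covariate-adjusted linear model and extract the exposure effect
#'
#' Ordinary least squares of the outcome on the exposure plus the model's
#' covariate set (categorical covariates entering as indicator
#' contrasts). Inference on the exposure coefficient uses the t
#' distribution with residual degrees of freedom.
#'
#' @param spec a [model_spec()].
#' @param table a complete (no missing cells among used columns) cohort
#'   table.
#' @return A one-row data frame of class \code{"fit_result"}: outcome,
#'   model, \code{B} (outcome units per 1-unit exposure), \code{se},
#'   \code{ci_low}, \code{ci_high}, \code{p}, \code{n}, \code{df}.
#' @export
fit_linear <- function(spec, table) {
  if (!is.null(spec$stratum))
    table <- table[table[[spec$stratum$column]] == spec$stratum$level, ,
                   drop = FALSE]
  if (!nrow(table)) stop("empty stratum: ", spec$stratum$level)
  use <- c(spec$outcome, spec$exposure, spec$covariates)
  miss <- setdiff(use, names(table))
  if (length(miss)) stop("table lacks column(s): ", paste(miss, collapse = ", "))
  dat <- table[use]
  if (anyNA(dat))
    stop("missing cells in model columns; impute or subset first")
  fml <- stats::reformulate(c(spec$exposure, spec$covariates),
                            response = spec$outcome)
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  b <- sm[spec$exposure, "Estimate"]; se <- sm[spec$exposure, "Std. Error"]
  df <- fit$df.residual
  tcrit <- stats::qt(0.975, df)
  p <- if (se == 0) as.numeric(b == 0) else
    2 * stats::pt(abs(b / se), df, lower.tail = FALSE)
  structure(data.frame(outcome = spec$outcome, model = spec$model,
                       stratum = if (is.null(spec$stratum)) NA_character_
                                 else paste0(spec$stratum$column, "=",
                                             spec$stratum$level),
                       B = b, se = se,
                       ci_low = b - tcrit * se, ci_high = b + tcrit * se,
                       p = p, n = nrow(dat), df = df,
                       stringsAsFactors = FALSE),
            class = c("fit_result", "data.frame"))
}

#' Benjamini-Hochberg adjustment within a test family
#'
#' Step-up FDR control: adjusted value
#' \eqn{q_{(i)} = \min_{j \ge i} m p_{(j)} / j}, capped at 1 and mapped
#' back to input order; a test is flagged significant when
#' \eqn{q \le} \code{fdr}.
#'
#' @param p numeric vector of raw two-sided p-values.
#' @param fdr the false-discovery rate (default 0.05).
#' @return List with \code{q} and logical \code{significant}.
#' @export
bh_adjust <- function(p, fdr = 0.05) {
  if (!length(p)) return(list(q = numeric(0), significant = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = q <= fdr)
}

family_outcomes <- function(family) {
  switch(family,
    volumes = c("tbv_10", "wm_10", "gm_10", "sub_10",
                "tbv_14", "wm_14", "gm_14", "sub_14"),
    iq = c("iq_14", "vocab_14", "matrix_14", "digit_14", "coding_14"),
    stop("unknown family: ", family))
}

#' Fit a whole outcome family with family-wise FDR control
#'
#' The volume family comprises the 4 global/subcortical volumes at each
#' of ages 10 and 14 (8 tests); the IQ family comprises full-scale IQ and
#' the 4 subtest t-scores at age 14 (5 tests). Benjamini-Hochberg
#' adjustment is applied within the family. Given an imputation set
#' (from [impute_chained()]), each outcome is fitted per completed
#' dataset and pooled by Rubin's rules before adjustment.
#'
#' @param table a cohort table, or an \code{imputation_set}.
#' @param family \code{"volumes"} or \code{"iq"}.
#' @param model 1 or 2.
#' @param fdr family false-discovery rate.
#' @param extras,stratum passed to [model_spec()].
#' @return Data frame with one row per outcome: the [fit_linear()]
#'   columns plus \code{q} and \code{significant}.
#' @export
run_family <- function(table, family = c("volumes", "iq"), model = 1,
                       fdr = 0.05, extras = character(), stratum = NULL) {
  family <- match.arg(family)
  outs <- family_outcomes(family)
  rows <- lapply(outs, function(o) {
    spec <- model_spec(o, model = model, extras = extras, stratum = stratum)
    if (inherits(table, "imputation_set")) {
      fits <- lapply(table$completed, function(d) fit_linear(spec, d))
      pool <- pool_rubin(vapply(fits, `[[`, 0, "B"),
                         vapply(fits, `[[`, 0, "se"),
                         dfcom = fits[[1]]$df)
      data.frame(outcome = o, model = model,
                 stratum = fits[[1]]$stratum,
                 B = pool$estimate, se = sqrt(pool$total_variance),
                 ci_low = pool$ci[1], ci_high = pool$ci[2],
                 p = pool$p, n = fits[[1]]$n, df = pool$df,
                 stringsAsFactors = FALSE)
    } else fit_linear(spec, table)
  })
  res <- do.call(rbind, rows)
  adj <- bh_adjust(res$p, fdr)
  res$q <- adj$q
  res$significant <- adj$significant
  res
}

#' Leave-one-food-component-out sensitivity analysis
#'
#' For each of the 15 score components, refits the main model with the
#' 14-component score as the exposure and the excluded component's intake
#' (its component score, for alcohol and folic acid) as an additional
#' covariate.
#'
#' @param table a complete cohort table carrying the raw intake columns.
#' @param registry the component registry.
#' @param outcome outcome column (default total brain volume at 10).
#' @param model 1 or 2.
#' @return Data frame with one row per excluded component.
#' @export
run_component_exclusion <- function(table, registry = default_registry(),
                                    outcome = "tbv_10", model = 1) {
  scores <- score_intake_table(table, registry)
  rows <- lapply(registry$name, function(comp) {
    tab <- table
    tab$diet_score_loo <- scores$diet_score -
      scores[[paste0("score_", comp)]]
    tab$excluded_intake <- switch(comp,
      alcohol = scores$score_alcohol,
      folic_acid = scores$score_folic_acid,
      table[[comp]])
    # a zero-variance excluded component is collinear with the intercept
    extras <- if (stats::var(tab$excluded_intake) > 0) "excluded_intake"
              else character(0)
    spec <- model_spec(outcome, model = model, exposure = "diet_score_loo",
                       extras = extras)
    out <- fit_linear(spec, tab)
    out$excluded <- comp
    out
  })
  do.call(rbind, rows)
}

#' Stratified analysis by a categorical covariate
#'
#' Repeats a fit within each level of the stratifier (by default maternal
#' national origin), dropping the stratifier from the covariate set.
#'
#' @param table a complete cohort table.
#' @param outcome outcome column.
#' @param stratifier stratifying covariate column.
#' @param model 1 or 2.
#' @return Data frame with one row per stratum.
#' @export
run_stratified <- function(table, outcome = "tbv_10", stratifier = "origin",
                           model = 1) {
  levs <- unique(as.character(table[[stratifier]]))
  if (length(levs) < 2) stop("stratifier has a single level")
  rows <- lapply(levs, function(lv) {
    fit_linear(model_spec(outcome, model = model,
                          stratum = list(column = stratifier, level = lv)),
               table)
  })
  do.call(rbind, rows)
}
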