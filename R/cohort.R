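# Synthetic mother-child cohort generator.
#
# A single latent socioeconomic factor U drives the categorical maternal
# covariates and, together with energy intake, the latent diet propensity
# from which component intakes are drawn. Brain volumes and IQ carry the
# configured diet effects plus a socioeconomic gradient expressed through
# an index built from the observed model covariates, so that
# covariate-adjusted regression identifies the configured effects while
# the crude regression is confounded upward.

.calib_cache <- new.env(parent = emptyenv())

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the pipeline is meant to emulate:
#' a maternal diet-quality score with mean 7.8 and SD 1.6, a
#' maternal-child diet correlation of 0.29, diet effects of 4.54 / 1.83 /
#' 1.99 / 0.16 cm\eqn{^3} per score unit on total brain, cerebral white,
#' cerebral gray and subcortical volumes, a total diet effect on
#' full-scale IQ of 0.65 points per unit of which 7.7\% runs through total
#' brain volume, and socioeconomic confounding.
#'
#' @param n_dyads number of mother-child pairs.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param score_mean,score_sd targets for the maternal diet-quality score
#'   distribution (score points, 0-15).
#' @param maternal_child_diet_corr target Pearson correlation between the
#'   maternal score and the child diet score at age 8.
#' @param effect_volume named vector: cm\eqn{^3} of brain volume per
#'   1-unit diet score, for \code{total_brain}, \code{cerebral_white},
#'   \code{cerebral_gray}, \code{subcortical}. The three tissue effects
#'   must not exceed the total-brain effect by more than the residual
#'   (cerebellum/brainstem) compartment can absorb.
#' @param effect_iq_total total diet effect on full-scale IQ, points per
#'   score unit.
#' @param proportion_mediated_total_brain fraction of the total IQ effect
#'   carried by the total-brain pathway (structural truth; the remaining
#'   volumes mediate only through their correlation with total brain).
#' @param confounding_strength loading of the latent socioeconomic factor
#'   on the diet propensity, in \[0, 1). At 0 the crude diet-outcome
#'   regression is unbiased.
#' @param missingness named vector of per-covariate missingness rates in
#'   \[0, 1) used by [inject_missingness()]; names must be covariate
#'   columns (never exposure, mediators or outcomes).
#' @param noise_sd named list of residual SDs: \code{wm}, \code{gm},
#'   \code{sub}, \code{other} (cm\eqn{^3}) and \code{iq} (points).
#' @return A list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_dyads = 2223,
                          seed = 1L,
                          score_mean = 7.8,
                          score_sd = 1.6,
                          maternal_child_diet_corr = 0.29,
                          effect_volume = c(total_brain = 4.54,
                                            cerebral_white = 1.83,
                                            cerebral_gray = 1.99,
                                            subcortical = 0.16),
                          effect_iq_total = 0.65,
                          proportion_mediated_total_brain = 0.077,
                          confounding_strength = 0.25,
                          missingness = c(education = 0.05, income = 0.10,
                                          smoking = 0.08, gsi = 0.15,
                                          child_diet_score = 0.20,
                                          breastfeeding = 0.25,
                                          folate_serum = 0.20),
                          noise_sd = list(wm = 55, gm = 65, sub = 5.5,
                                          other = 15, iq = 13)) {
  cfg <- list(n_dyads = n_dyads, seed = seed,
              score_mean = score_mean, score_sd = score_sd,
              maternal_child_diet_corr = maternal_child_diet_corr,
              effect_volume = effect_volume,
              effect_iq_total = effect_iq_total,
              proportion_mediated_total_brain = proportion_mediated_total_brain,
              confounding_strength = confounding_strength,
              missingness = missingness, noise_sd = noise_sd)
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_dyads >= 1,
            cfg$score_mean >= 0, cfg$score_mean <= 15, cfg$score_sd >= 0,
            abs(cfg$maternal_child_diet_corr) <= 1,
            cfg$confounding_strength >= 0, cfg$confounding_strength < 1)
  need <- c("total_brain", "cerebral_white", "cerebral_gray", "subcortical")
  if (!all(need %in% names(cfg$effect_volume)))
    stop("effect_volume must name: ", paste(need, collapse = ", "))
  pm <- cfg$proportion_mediated_total_brain
  if (pm < 0 || pm > 1)
    stop("proportion mediated must lie in [0, 1]")
  if (cfg$effect_volume[["total_brain"]] == 0 && pm > 0)
    stop("proportion mediated > 0 requires a non-zero total-brain effect")
  if (any(cfg$missingness < 0) || any(cfg$missingness >= 1))
    stop("missingness rates must lie in [0, 1)")
  if (any(unlist(cfg$noise_sd) <= 0)) stop("noise SDs must be positive")
  invisible(cfg)
}

# Fixed per-component latent-intake parameters: median intake as a
# fraction of the cut-off before calibration shifts, and log-scale /
# probit spreads. Chosen once to give realistic intake distributions.
intake_model_params <- function() {
  list(
    med_adeq = c(vegetables = 0.65, fruit = 0.75, whole_grains = 0.55,
                 legumes = 0.40, nuts = 0.40, dairy = 0.80, fish = 0.50,
                 tea = 0.60),
    med_mod = c(red_meat = 0.90, sugary_beverages = 0.80, salt = 1.00),
    s_adeq = 0.7, s_mod = 0.6, b_ratio = 0.7,
    ratio_base = c(grain_quality_ratio = stats::qnorm(0.45),
                   soft_fat_ratio = stats::qnorm(0.55)),
    alcohol_base = 0.4, alcohol_load = 0.8,
    folic_cut = stats::qnorm(c(0.45, 0.15))  # periconceptional / first-10-wk
  )
}

# Draw component intakes for n mothers with latent diet propensity D
# (standard normal). delta shifts every component toward (delta > 0)
# healthier intakes; r is the shared loading of D on each component.
draw_intakes <- function(n, D, delta, r) {
  p <- intake_model_params()
  reg <- default_registry()
  cut <- stats::setNames(reg$cutoff, reg$name)
  lat <- function() r * D + sqrt(1 - r^2) * stats::rnorm(n)
  tab <- data.frame(row.names = seq_len(n))
  for (nm in names(p$med_adeq))
    tab[[nm]] <- cut[[nm]] * exp(log(p$med_adeq[[nm]]) + delta + p$s_adeq * lat())
  for (nm in names(p$med_mod))
    tab[[nm]] <- cut[[nm]] * exp(log(p$med_mod[[nm]]) - delta - p$s_mod * lat())
  for (nm in names(p$ratio_base))
    tab[[nm]] <- stats::pnorm(p$ratio_base[[nm]] + delta + p$b_ratio * lat())
  tab$alcohol_any <- stats::runif(n) >
    stats::plogis(p$alcohol_base + delta + p$alcohol_load * D)
  fl <- lat() + delta
  tab$folic_acid <- ifelse(fl > p$folic_cut[1], "periconceptional",
                    ifelse(fl > p$folic_cut[2], "first_10_weeks", "none"))
  tab
}

#' Calibrate the intake distributions to score targets
#'
#' Finds, by seeded stochastic search (alternating bisection on Monte
#' Carlo evaluations with common random numbers), the global intake shift
#' and latent-loading parameters under which the scored 15-component total
#' matches the target mean within 0.05 and the target SD within 0.1.
#' Results are cached per (mean, SD, seed) triple for the session.
#'
#' The degenerate targets (15, 0) and (0, 0) are honoured exactly with
#' all-at-cut-off and all-zero intake distributions respectively.
#'
#' @param score_mean,score_sd targets for the total score distribution.
#' @param seed seed of the calibration search itself (fixed by default so
#'   that the same targets always yield the same parameters).
#' @param n_eval Monte Carlo sample size per objective evaluation.
#' @param max_rounds alternating-bisection rounds before giving up.
#' @return List with \code{delta} (intake shift), \code{r} (latent
#'   loading), \code{achieved_mean}, \code{achieved_sd}, or a
#'   \code{degenerate} marker for the boundary targets.
#' @export
calibrate_intakes <- function(score_mean, score_sd, seed = 20151101L,
                              n_eval = 20000, max_rounds = 8) {
  if (score_mean == 15 && score_sd == 0) return(list(degenerate = "max"))
  if (score_mean == 0 && score_sd == 0) return(list(degenerate = "min"))
  if (score_mean < 0 || score_mean > 15)
    stop("score_mean outside the feasible [0, 15] range")
  if (score_sd <= 0)
    stop("a zero score SD is only feasible at the 0 or 15 boundary")
  key <- paste(score_mean, score_sd, seed, n_eval, sep = "|")
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])

  evaluate <- function(delta, r) with_seed(seed, {
    D <- stats::rnorm(n_eval)
    s <- score_intake_table(draw_intakes(n_eval, D, delta, r))$diet_score
    c(mean = mean(s), sd = stats::sd(s))
  })
  delta <- 0; r <- 0.3
  for (round in seq_len(max_rounds)) {
    # mean is monotone increasing in delta at fixed r
    lo <- -4; hi <- 2.5
    for (i in 1:18) {
      delta <- (lo + hi) / 2
      if (evaluate(delta, r)[["mean"]] < score_mean) lo <- delta else hi <- delta
    }
    # sd is monotone increasing in r at fixed delta
    lo <- 0.001; hi <- 0.97
    for (i in 1:14) {
      r <- (lo + hi) / 2
      if (evaluate(delta, r)[["sd"]] < score_sd) lo <- r else hi <- r
    }
    got <- evaluate(delta, r)
    if (abs(got[["mean"]] - score_mean) < 0.05 &&
        abs(got[["sd"]] - score_sd) < 0.1) {
      out <- list(delta = delta, r = r,
                  achieved_mean = got[["mean"]], achieved_sd = got[["sd"]],
                  n_eval = n_eval, seed = seed)
      .calib_cache[[key]] <- out
      return(out)
    }
  }
  stop(sprintf(paste0("intake calibration did not converge for targets ",
                      "(%.2f, %.2f); best achieved (%.3f, %.3f)"),
               score_mean, score_sd, got[["mean"]], got[["sd"]]))
}

# Intakes that score exactly 15 (resp. 0) on every component. Note the
# zero-score boundary needs moderation intakes at twice the cut-off:
# zero intake of a moderation food earns full credit, not zero.
degenerate_intakes <- function(n, which) {
  reg <- default_registry()
  tab <- data.frame(row.names = seq_len(n))
  for (nm in setdiff(reg$name, c("alcohol", "folic_acid"))) {
    k <- reg$kind[reg$name == nm]
    tab[[nm]] <- if (which == "max") {
      if (k == "moderation") 0 else reg$cutoff[reg$name == nm]
    } else {
      if (k == "moderation") 2 * reg$cutoff[reg$name == nm] else 0
    }
  }
  tab$alcohol_any <- which != "max"
  tab$folic_acid <- if (which == "max") "periconceptional" else "none"
  tab
}

# Socioeconomic index over the observed model-1 covariates. Lies in the
# column span of the model-1 design matrix by construction, so adjusted
# regression identifies the diet effects exactly.
ses_index <- function(tab) {
  0.45 * (tab$education == "high") +
    0.40 * (tab$income == "gt2200") + 0.18 * (tab$income == "eur1200_2200") +
    0.18 * (tab$origin == "dutch") -
    0.12 * (tab$smoking == "until_known") - 0.25 * (tab$smoking == "continued") -
    0.20 * pmin(tab$gsi, 2) +
    0.015 * (tab$maternal_age - 31.2)
}

#' Generate a complete synthetic mother-child cohort
#'
#' Draws \code{n_dyads} rows of maternal covariates, component-level
#' dietary intakes (scored into the 0-15 diet-quality total), child
#' covariates, brain volumes at ages 10 and 14 (cm\eqn{^3}), full-scale
#' IQ and WISC-style subtest t-scores, with the effect structure set by
#' the configuration. The returned table is complete;
#' [inject_missingness()] adds missing covariate cells.
#'
#' The generative truth (structural coefficients actually used) is
#' attached as \code{attr(table, "truth")}.
#'
#' @param config a [cohort_config()].
#' @return A data frame (one row per dyad) with maternal covariates,
#'   intake columns, \code{diet_score}, child covariates, volume columns
#'   (\code{tbv_10} ... \code{icv_14}), IQ/subtest columns and nutrient
#'   proxy columns \code{fiber_proxy}, \code{satfat_proxy}.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_config(config)
  cal <- calibrate_intakes(config$score_mean, config$score_sd)

  with_seed(config$seed, {
    n <- config$n_dyads
    U <- stats::rnorm(n)  # latent socioeconomic factor

    # --- maternal covariates ------------------------------------------
    tab <- data.frame(id = sprintf("dyad%05d", seq_len(n)))
    tab$maternal_age <- 31.2 + 4.6 * (0.3 * U + sqrt(1 - 0.09) * stats::rnorm(n))
    tab$education <- factor(ifelse(0.7 * U + sqrt(0.51) * stats::rnorm(n) >
                                     stats::qnorm(1 - 0.656), "high", "low"),
                            levels = c("high", "low"))
    inc <- 0.8 * U + 0.6 * stats::rnorm(n)
    tab$income <- factor(ifelse(inc < stats::qnorm(0.12), "lt1200",
                         ifelse(inc < stats::qnorm(0.34), "eur1200_2200",
                                "gt2200")),
                         levels = c("gt2200", "eur1200_2200", "lt1200"))
    tab$origin <- factor(ifelse(0.4 * U + sqrt(0.84) * stats::rnorm(n) >
                                  stats::qnorm(1 - 0.639), "dutch", "non_dutch"),
                         levels = c("dutch", "non_dutch"))
    smk <- -0.5 * U + sqrt(0.75) * stats::rnorm(n)
    tab$smoking <- factor(ifelse(smk > stats::qnorm(1 - 0.123), "continued",
                          ifelse(smk > stats::qnorm(1 - 0.215), "until_known",
                                 "never")),
                          levels = c("never", "until_known", "continued"))
    tab$gsi <- exp(-1.5 - 0.4 * U + 0.5 * stats::rnorm(n))
    e_std <- 0.1 * U + sqrt(0.99) * stats::rnorm(n)
    tab$energy_kcal <- pmax(2100 + 500 * e_std, 600)
    tab$folate_serum <- pmax(17 + 8 * (0.3 * U + 0.95 * stats::rnorm(n)), 2)
    bf <- 0.4 * U + sqrt(0.84) * stats::rnorm(n)
    tab$breastfeeding <- factor(ifelse(bf > stats::qnorm(0.6), "ge6mo",
                                ifelse(bf > stats::qnorm(0.15), "lt6mo",
                                       "never")),
                                levels = c("ge6mo", "lt6mo", "never"))

    # --- dietary intakes and the exposure score -----------------------
    qu <- config$confounding_strength; qe <- 0.15
    D <- qu * U + qe * e_std + sqrt(max(1 - qu^2 - qe^2, 0)) * stats::rnorm(n)
    intakes <- if (!is.null(cal$degenerate))
      degenerate_intakes(n, cal$degenerate)
    else draw_intakes(n, D, cal$delta, cal$r)
    tab <- cbind(tab, intakes)
    tab$diet_score <- score_intake_table(intakes)$diet_score
    s_z <- if (config$score_sd > 0)
      (tab$diet_score - config$score_mean) / config$score_sd
    else rep(0, n)

    # nutrient proxies for the internal-validity sign check
    tab$fiber_proxy <- 0.02 * tab$vegetables + 0.02 * tab$fruit +
      0.05 * tab$whole_grains + 0.01 * tab$legumes / 7 +
      0.1 * tab$nuts + stats::rnorm(n, 0, 2)
    tab$satfat_proxy <- 0.025 * tab$red_meat / 7 +
      12 * (1 - tab$soft_fat_ratio) + 0.002 * tab$dairy + stats::rnorm(n, 0, 2)

    # --- child covariates ---------------------------------------------
    tab$child_sex <- factor(ifelse(stats::runif(n) < 0.505, "girl", "boy"),
                            levels = c("girl", "boy"))
    tab$child_age_10 <- 9.7 + stats::rgamma(n, shape = 2, scale = 0.15)
    tab$child_age_14 <- 13.5 + stats::rgamma(n, shape = 2, scale = 0.20)
    rho <- config$maternal_child_diet_corr
    tab$child_diet_score <- pmin(pmax(
      4.5 + 1.2 * (rho * s_z + sqrt(1 - rho^2) * stats::rnorm(n)), 0), 10)

    # --- brain volumes -------------------------------------------------
    ev <- config$effect_volume
    e_oth <- ev[["total_brain"]] - ev[["cerebral_white"]] -
      ev[["cerebral_gray"]] - ev[["subcortical"]]
    ses <- ses_index(tab)
    boy <- as.numeric(tab$child_sex == "boy")
    ns <- config$noise_sd
    S <- tab$diet_score
    wm <- 400 + ev[["cerebral_white"]] * S + 25 * ses + 35 * boy +
      stats::rnorm(n, 0, ns$wm)
    gm <- 600 + ev[["cerebral_gray"]] * S + 30 * ses + 45 * boy +
      stats::rnorm(n, 0, ns$gm)
    sub <- 55 + ev[["subcortical"]] * S + 2.5 * ses + 3 * boy +
      stats::rnorm(n, 0, ns$sub)
    oth <- 135 + e_oth * S + 5 * ses + 8 * boy + stats::rnorm(n, 0, ns$other)
    csf <- 120 * exp(stats::rnorm(n, 0, 0.15))
    tab$wm_10 <- wm; tab$gm_10 <- gm; tab$sub_10 <- sub
    tab$tbv_10 <- wm + gm + sub + oth
    tab$icv_10 <- tab$tbv_10 + csf
    wm4 <- wm + 25 + stats::rnorm(n, 0, 8)
    gm4 <- gm - 25 + stats::rnorm(n, 0, 10)
    sub4 <- sub + 2 + stats::rnorm(n, 0, 1.5)
    oth4 <- oth + 5 + stats::rnorm(n, 0, 4)
    tab$wm_14 <- wm4; tab$gm_14 <- gm4; tab$sub_14 <- sub4
    tab$tbv_14 <- wm4 + gm4 + sub4 + oth4
    tab$icv_14 <- tab$tbv_14 + csf * exp(stats::rnorm(n, 0, 0.05))

    # --- cognition ------------------------------------------------------
    pm <- config$proportion_mediated_total_brain
    acme <- config$effect_iq_total * pm
    b <- if (ev[["total_brain"]] != 0) acme / ev[["total_brain"]] else 0
    c_dir <- config$effect_iq_total - acme
    mean_tbv <- 400 + 600 + 55 + 135 + ev[["total_brain"]] * config$score_mean +
      91 * 0.495
    iq0 <- 103.5 - c_dir * config$score_mean - b * mean_tbv
    tab$iq_14 <- iq0 + c_dir * S + b * tab$tbv_10 + 12 * ses +
      stats::rnorm(n, 0, ns$iq)
    tscore <- function(base, eff, ses_w, sd) {
      raw <- base + eff * (S - config$score_mean) + ses_w * ses +
        stats::rnorm(n, 0, sd)
      pmin(pmax(round(raw), 1), 19)
    }
    tab$vocab_14 <- tscore(10.0, 0.14, 0.8, 2.8)
    tab$matrix_14 <- tscore(9.5, 0.16, 0.8, 2.6)
    tab$digit_14 <- tscore(9.8, 0.00, 0.5, 2.7)
    tab$coding_14 <- tscore(13.0, 0.00, 0.4, 3.2)

    attr(tab, "truth") <- list(
      effect_volume = ev, effect_other_compartment = e_oth,
      effect_iq_direct = c_dir, effect_tbv_on_iq = b, acme = acme,
      effect_iq_total = config$effect_iq_total,
      proportion_mediated_total_brain = pm,
      seed = config$seed, calibration = cal[c("delta", "r")])
    tab
  })
}

#' Inject missing-at-random covariate cells
#'
#' Sets covariate cells to \code{NA} with probabilities that depend only
#' on always-observed variables (maternal age and child sex), i.e. an MAR
#' mechanism. Exposure-score inputs, mediators and outcomes are never made
#' missing, matching the scope of the downstream imputation.
#'
#' @param table a cohort table from [generate_cohort()].
#' @param config a [cohort_config()]; \code{config$missingness} gives the
#'   per-covariate target rates.
#' @param seed optional seed (defaults to a seed derived from the config).
#' @return The table with missing covariate cells.
#' @export
inject_missingness <- function(table, config = cohort_config(),
                               seed = derive_seed(config$seed, 2L)) {
  rates <- config$missingness
  protected <- c("id", "diet_score", grep("^(tbv|wm|gm|sub|icv)_", names(table),
                                          value = TRUE),
                 c("iq_14", "vocab_14", "matrix_14", "digit_14", "coding_14"),
                 setdiff(default_registry()$name, c("alcohol", "folic_acid")),
                 c("alcohol_any", "folic_acid"),
                 "maternal_age", "child_sex")
  bad <- intersect(names(rates), protected)
  if (length(bad))
    stop("missingness not allowed in exposure/mediator/outcome column(s): ",
         paste(bad, collapse = ", "))
  missing_cols <- setdiff(names(rates)[rates > 0], character(0))
  if (!length(missing_cols)) return(table)
  with_seed(seed, {
    z_age <- as.numeric(scale(table$maternal_age))
    girl <- as.numeric(table$child_sex == "girl")
    lin <- 0.5 * z_age - 0.3 * girl
    for (col in missing_cols) {
      if (!col %in% names(table)) stop("unknown covariate column: ", col)
      # solve the intercept so the marginal rate matches the target
      a <- stats::uniroot(function(a) mean(stats::plogis(a + lin)) - rates[[col]],
                          c(-20, 20))$root
      hit <- stats::runif(nrow(table)) < stats::plogis(a + lin)
      table[[col]][hit] <- NA
    }
    table
  })
}
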