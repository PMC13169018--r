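# End-to-end orchestration: generate -> score -> (inject/impute) ->
# associate -> mediate, with per-stage seeds derived from one global
# seed, a config hash stamped into every artifact, and CSV/JSON outputs.

#' Pipeline configuration
#'
#' @param cohort a [cohort_config()] (its \code{seed} is overridden by a
#'   seed derived from \code{seed} below).
#' @param imputation \code{"complete-case"} or a list
#'   \code{list(m =, iterations =)}; imputation only runs when the
#'   cohort config injects missingness.
#' @param models which adjustment models to run (subset of \code{1:2}).
#' @param mediators mediator columns for the mediation stage.
#' @param n_sims quasi-Bayesian draws per mediation.
#' @param seed global seed; all stage seeds derive from it.
#' @param outdir output directory (created if needed); \code{NULL} for
#'   in-memory results only.
#' @return A list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            imputation = "complete-case",
                            models = c(1, 2),
                            mediators = c("tbv_10", "wm_10", "gm_10", "sub_10"),
                            n_sims = 1000,
                            seed = 1L,
                            outdir = NULL) {
  structure(list(cohort = cohort, imputation = imputation, models = models,
                 mediators = mediators, n_sims = n_sims, seed = seed,
                 outdir = outdir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL  # where results land does not change what they are
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE,
                              digits = 12), f)
  unname(tools::md5sum(f))
}

#' Describe a cohort table
#'
#' One row per variable: mean (SD) for continuous variables with
#' |skewness| <= 1, median (IQR) for skewed continuous variables, and
#' per-level percentages for categorical variables.
#'
#' @param table a cohort table.
#' @param skew_threshold |skewness| above which median/IQR is reported.
#' @return Data frame with columns \code{variable}, \code{level},
#'   \code{statistic}, \code{value1}, \code{value2} (SD, or the IQR
#'   bounds pasted, or NA for percentages).
#' @export
describe_cohort <- function(table, skew_threshold = 1) {
  keep <- setdiff(names(table), "id")
  rows <- lapply(keep, function(v) {
    x <- table[[v]]
    if (is.numeric(x)) {
      if (abs(skewness(x)) > skew_threshold) {
        q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
        data.frame(variable = v, level = NA, statistic = "median (IQR)",
                   value1 = q[[2]], value2 = paste0(round(q[[1]], 2), ", ",
                                                    round(q[[3]], 2)))
      } else {
        data.frame(variable = v, level = NA, statistic = "mean (SD)",
                   value1 = mean(x, na.rm = TRUE),
                   value2 = as.character(round(stats::sd(x, na.rm = TRUE), 3)))
      }
    } else {
      x <- factor(x)
      pct <- 100 * as.numeric(table(x)) / sum(!is.na(x))
      data.frame(variable = v, level = levels(x), statistic = "%",
                 value1 = pct, value2 = NA_character_)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Generates the synthetic cohort, injects missingness if configured,
#' imputes or restricts to complete cases, fits both outcome families
#' under the requested models with family-wise BH correction, and runs
#' the quasi-Bayesian mediation for each configured mediator. Fully
#' deterministic given the global seed.
#'
#' @param config a [pipeline_config()].
#' @return List of class \code{"pipeline_result"}: \code{cohort_description},
#'   \code{associations} (one data frame, all families/models),
#'   \code{mediation} (per-mediator summary data frame and the raw
#'   results), \code{config_hash}, \code{seeds}, \code{log}. When
#'   \code{config$outdir} is set, CSV/JSON artifacts and a MANIFEST are
#'   written there too.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  hash <- config_hash(config)
  seeds <- list(cohort = derive_seed(config$seed, 1L),
                missing = derive_seed(config$seed, 2L),
                impute = derive_seed(config$seed, 3L),
                mediate = derive_seed(config$seed, 4L))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  stage <- "generate"
  result <- tryCatch({
    ccfg <- config$cohort
    ccfg$seed <- seeds$cohort
    cohort <- generate_cohort(ccfg)
    note("generate: n=", nrow(cohort), " seed=", seeds$cohort)

    any_missing <- any(ccfg$missingness > 0)
    if (any_missing) {
      stage <- "inject_missingness"
      cohort_mis <- inject_missingness(cohort, ccfg, seed = seeds$missing)
      note("missingness: ", sum(is.na(cohort_mis)), " cells, seed=",
           seeds$missing)
    } else cohort_mis <- cohort

    stage <- "impute"
    use_mi <- is.list(config$imputation) && any_missing
    analysis_input <- if (use_mi) {
      imp <- impute_chained(cohort_mis, m = config$imputation$m,
                            iterations = config$imputation$iterations,
                            seed = seeds$impute)
      note("impute: m=", imp$m, " iterations=", imp$iterations,
           " seed=", seeds$impute)
      imp
    } else {
      cc <- cohort_mis[stats::complete.cases(cohort_mis), , drop = FALSE]
      note("complete-case: ", nrow(cc), " of ", nrow(cohort_mis), " rows")
      cc
    }

    stage <- "associate"
    assoc <- do.call(rbind, lapply(config$models, function(md) {
      rbind(cbind(family = "volumes",
                  run_family(analysis_input, "volumes", model = md)),
            cbind(family = "iq",
                  run_family(analysis_input, "iq", model = md)))
    }))
    note("associate: ", nrow(assoc), " fits")

    stage <- "mediate"
    med <- lapply(config$mediators, function(mcol) {
      spec <- mediation_spec(mediator = mcol, n_sims = config$n_sims,
                             seed = seeds$mediate)
      if (inherits(analysis_input, "imputation_set"))
        mediate_pooled(spec, analysis_input)
      else mediate_quasi_bayes(spec, analysis_input)
    })
    names(med) <- config$mediators
    med_table <- do.call(rbind, lapply(config$mediators, function(mcol) {
      r <- med[[mcol]]
      data.frame(mediator = mcol, acme = r$acme, ade = r$ade,
                 total = r$total, proportion_mediated = r$proportion_mediated,
                 acme_lo = unname(r$ci$acme[1]), acme_hi = unname(r$ci$acme[2]),
                 total_lo = unname(r$ci$total[1]),
                 total_hi = unname(r$ci$total[2]))
    }))
    note("mediate: ", length(med), " mediators, ", config$n_sims,
         " draws, seed=", seeds$mediate)

    stage <- "describe"
    desc <- describe_cohort(cohort)

    list(cohort_description = desc, associations = assoc,
         mediation = list(summary = med_table, results = med),
         config_hash = hash, seeds = seeds, log = log)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  class(result) <- "pipeline_result"
  if (!is.null(config$outdir)) write_pipeline_outputs(result, config)
  result
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  done <- character(0)
  emit <- function(f, writer) {
    writer(out(f)); done <<- c(done, f)
  }
  emit("cohort_description.csv", function(f)
    utils::write.csv(result$cohort_description, f, row.names = FALSE))
  emit("associations.csv", function(f)
    utils::write.csv(result$associations, f, row.names = FALSE))
  emit("mediation.csv", function(f)
    utils::write.csv(result$mediation$summary, f, row.names = FALSE))
  emit("run.json", function(f)
    jsonlite::write_json(list(config_hash = result$config_hash,
                              seeds = result$seeds, log = result$log),
                         f, auto_unbox = TRUE, pretty = TRUE))
  writeLines(c(paste("config_hash:", result$config_hash), "complete: true",
               paste("file:", done)),
             out("MANIFEST"))
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result (config ", substr(x$config_hash, 1, 8), ")\n", sep = "")
  cat(" associations:\n")
  print(x$associations[c("family", "model", "outcome", "B", "ci_low",
                         "ci_high", "q", "significant")], digits = 3)
  cat(" mediation:\n")
  print(x$mediation$summary, digits = 3)
  invisible(x)
}
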