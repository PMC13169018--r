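# Multiple imputation of covariates by chained equations, and Rubin's
# rules for pooling estimates across completed datasets.
#
# Continuous covariates are imputed by Bayesian linear regression draws
# (posterior draw of sigma^2 and beta, then a residual draw); categorical
# covariates by a multinomial-logistic model fitted on a bootstrap
# resample of the complete cases (the bootstrap supplies the parameter
# uncertainty), falling back to an observed-category frequency draw if
# the model fails. The imputation models are congenial: they include the
# exposure score, the key mediator and the outcome as predictors.

default_imputation_predictors <- function(table) {
  cand <- c("maternal_age", "education", "income", "origin", "smoking",
            "gsi", "energy_kcal", "folate_serum", "breastfeeding",
            "child_sex", "child_diet_score",
            "diet_score", "tbv_10", "iq_14")
  intersect(cand, names(table))
}

#' Multiple imputation by chained equations
#'
#' Fills missing covariate cells in \code{m} independent chains of
#' \code{iterations} sweeps each. Per sweep, every incomplete column is
#' regressed on the other predictors over the rows where it is observed,
#' and its missing cells are redrawn from the fitted predictive
#' distribution. Observed cells are never altered.
#'
#' @param table cohort table with missing cells confined to covariates.
#' @param m number of completed datasets (default 10).
#' @param iterations chained-equation sweeps per chain (default 50).
#' @param seed integer seed; the whole set is deterministic given it.
#' @param predictors columns used as predictors in every imputation
#'   model; defaults to the model covariates plus exposure, total brain
#'   volume and IQ (congenial imputation).
#' @return An object of class \code{"imputation_set"}: list with
#'   \code{completed} (list of m complete tables), \code{m},
#'   \code{iterations}, \code{seed} and \code{imputed_columns}.
#' @export
impute_chained <- function(table, m = 10, iterations = 50, seed = 1L,
                           predictors = default_imputation_predictors(table)) {
  stopifnot(m >= 1, iterations >= 1)
  na_cols <- names(table)[vapply(table, anyNA, TRUE)]
  if (length(bad <- intersect(na_cols,
                              c("diet_score", "iq_14", "tbv_10", "tbv_14"))))
    stop("missingness must be confined to covariates; found NA in: ",
         paste(bad, collapse = ", "))
  for (col in na_cols)
    if (all(is.na(table[[col]])))
      stop("column with no observed values: ", col)
  if (!length(na_cols)) {
    out <- list(completed = rep(list(table), m), m = m,
                iterations = iterations, seed = seed,
                imputed_columns = character(0))
    class(out) <- "imputation_set"
    return(out)
  }

  completed <- with_seed(seed, lapply(seq_len(m), function(chain) {
    tab <- table
    # initialise missing cells by sampling observed values
    for (col in na_cols) {
      nas <- is.na(tab[[col]])
      tab[[col]][nas] <- sample(tab[[col]][!nas], sum(nas), replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (col in na_cols) {
        nas <- is.na(table[[col]])
        preds <- setdiff(predictors, col)
        X <- stats::model.matrix(stats::reformulate(preds), data = tab)
        tab[[col]][nas] <- if (is.numeric(table[[col]]))
          draw_continuous(table[[col]][!nas], X[!nas, , drop = FALSE],
                          X[nas, , drop = FALSE])
        else draw_categorical(tab, col, preds, obs = !nas, mis = nas)
      }
    }
    tab
  }))
  out <- list(completed = completed, m = m, iterations = iterations,
              seed = seed, imputed_columns = na_cols)
  class(out) <- "imputation_set"
  out
}

# Bayesian linear regression draw: sigma^2 from the scaled inverse
# chi-square posterior, beta from its conditional normal, then y_mis from
# the predictive normal.
draw_continuous <- function(y_obs, X_obs, X_mis) {
  qr_x <- qr(X_obs)
  keep <- qr_x$pivot[seq_len(qr_x$rank)]
  X_obs <- X_obs[, keep, drop = FALSE]; X_mis <- X_mis[, keep, drop = FALSE]
  fit <- stats::lm.fit(X_obs, y_obs)
  df <- length(y_obs) - ncol(X_obs)
  if (df < 2) return(sample(y_obs, nrow(X_mis), replace = TRUE))
  sigma2 <- sum(fit$residuals^2) / stats::rchisq(1, df)
  xtx_inv <- chol2inv(chol(crossprod(X_obs) +
                             diag(1e-8, ncol(X_obs))))
  beta <- fit$coefficients +
    drop(MASS::mvrnorm(1, rep(0, ncol(X_obs)), sigma2 * xtx_inv))
  drop(X_mis %*% beta) + stats::rnorm(nrow(X_mis), 0, sqrt(sigma2))
}

# Multinomial-logistic draw on a bootstrap resample of the observed rows.
draw_categorical <- function(tab, col, preds, obs, mis) {
  y_obs <- factor(tab[[col]][obs])
  freq_draw <- function()
    sample(levels(y_obs), sum(mis), replace = TRUE,
           prob = as.numeric(table(y_obs)) / sum(obs))
  probs <- tryCatch({
    boot <- sample(which(obs), sum(obs), replace = TRUE)
    dat <- tab[boot, preds, drop = FALSE]
    dat$.y <- factor(tab[[col]][boot], levels = levels(y_obs))
    if (nlevels(droplevels(dat$.y)) < 2) stop("degenerate bootstrap")
    fit <- nnet::multinom(stats::reformulate(preds, response = ".y"),
                          data = dat, trace = FALSE, maxit = 200)
    p <- stats::predict(fit, newdata = tab[mis, preds, drop = FALSE],
                        type = "probs")
    if (nlevels(y_obs) == 2) {
      p <- cbind(1 - p, p)          # predict() gives P(second level)
      colnames(p) <- levels(y_obs)
    } else if (is.null(dim(p))) {
      p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
    }
    p
  }, error = function(e) {
    warning("multinomial imputation model failed for '", col,
            "'; falling back to frequency draw", call. = FALSE)
    NULL
  })
  if (is.null(probs)) return(freq_draw())
  apply(probs, 1, function(pr)
    sample(colnames(probs), 1, prob = pmax(pr, 0)))
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Point estimate is the mean of the per-imputation estimates; the total
#' variance is \eqn{T = W + (1 + 1/m) B} with within-variance \eqn{W}
#' (mean squared SE) and between-variance \eqn{B}. The 95\% CI uses the t
#' distribution with Barnard-Rubin small-sample degrees of freedom when a
#' complete-data df is supplied.
#'
#' @param points numeric vector of per-imputation point estimates.
#' @param ses matching standard errors.
#' @param dfcom complete-data residual degrees of freedom (\code{Inf} for
#'   the large-sample Rubin df).
#' @return List of class \code{"pooled_estimate"}: \code{estimate},
#'   \code{within}, \code{between}, \code{total_variance}, \code{df},
#'   \code{ci} (length 2), \code{p}, \code{m}.
#' @export
pool_rubin <- function(points, ses, dfcom = Inf) {
  m <- length(points)
  if (m < 2) stop("pooling requires at least 2 imputations")
  if (length(ses) != m || any(!is.finite(ses))) stop("need m finite SEs")
  qbar <- mean(points)
  W <- mean(ses^2)
  B <- stats::var(points)
  T <- W + (1 + 1 / m) * B
  if (B == 0) {
    df <- if (is.finite(dfcom)) dfcom else Inf
  } else {
    lambda <- (1 + 1 / m) * B / T
    df_old <- (m - 1) / lambda^2
    df <- if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df_old * df_obs / (df_old + df_obs)
    } else df_old
  }
  se <- sqrt(T)
  tcrit <- stats::qt(0.975, df)
  p <- if (se == 0) as.numeric(qbar == 0) else
    2 * stats::pt(abs(qbar / se), df, lower.tail = FALSE)
  structure(list(estimate = qbar, within = W, between = B,
                 total_variance = T, df = df,
                 ci = c(qbar - tcrit * se, qbar + tcrit * se),
                 p = p, m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled estimate %.4g (95%% CI %.4g, %.4g), m = %d, df = %.1f\n",
              x$estimate, x$ci[1], x$ci[2], x$m, x$df))
  invisible(x)
}
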