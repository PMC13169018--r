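# Component scoring rules for the 0-15 pregnancy diet-quality index.
# All component scores live in [0, 1]; the total is their sum.

#' Score an adequacy food component
#'
#' Adequacy components reward intake up to a recommended minimum: the score
#' is the ratio of reported to recommended intake, truncated at 1. A fruit
#' intake of 120 g/d against the 200 g/d recommendation scores 0.6.
#'
#' @param intake non-negative intake in the component's unit (vectorised).
#' @param cutoff positive recommended intake in the same unit.
#' @return Score(s) in \[0, 1\].
#' @examples
#' score_adequacy_component(120, 200)  # 0.6
#' @export
score_adequacy_component <- function(intake, cutoff) {
  check_amounts(intake, cutoff)
  pmin(intake / cutoff, 1)
}

#' Score a moderation food component
#'
#' Moderation components (red meat, sugar-containing beverages, salt) are
#' reverse-coded: higher scores reflect lower intake. Full credit is given
#' at or below the recommended maximum, declining linearly to 0 at twice
#' the maximum: score = clamp(2 - intake/cutoff, 0, 1).
#'
#' @inheritParams score_adequacy_component
#' @return Score(s) in \[0, 1\].
#' @examples
#' score_moderation_component(750, 375)  # 0
#' @export
score_moderation_component <- function(intake, cutoff) {
  check_amounts(intake, cutoff)
  pmin(pmax(2 - intake / cutoff, 0), 1)
}

#' Score a dietary-ratio component
#'
#' Grain quality (whole grains / total grains) and soft fats and oils
#' (fraction of total fat) are scored as the ratio itself. An undefined
#' ratio (zero denominator in the source data, supplied as \code{NA}) is
#' scored 0 with a warning, so unobserved quality earns no credit.
#'
#' @param ratio fraction(s) in \[0, 1\], or \code{NA} for an undefined ratio.
#' @return Score(s) in \[0, 1\].
#' @export
score_ratio_component <- function(ratio) {
  undef <- is.na(ratio)
  if (any(undef)) {
    warning("undefined ratio component (zero denominator) scored 0 for ",
            sum(undef), " record(s)")
    ratio[undef] <- 0
  }
  if (any(ratio < 0 | ratio > 1))
    stop("ratio component values must lie in [0, 1]")
  ratio
}

#' Score the alcohol component
#'
#' No alcohol intake scores 1; any alcohol intake scores 0.
#'
#' @param alcohol_any logical (vectorised): any alcohol intake reported?
#' @return 0 or 1.
#' @export
score_alcohol <- function(alcohol_any) {
  if (!is.logical(alcohol_any) || anyNA(alcohol_any))
    stop("alcohol_any must be TRUE/FALSE")
  as.numeric(!alcohol_any)
}

#' Score the folic-acid supplement component
#'
#' Periconceptional supplement use scores 1, initiation within the first
#' 10 weeks of gestation scores 0.5, and no use in these periods scores 0.
#'
#' @param category character (vectorised): one of
#'   \code{"periconceptional"}, \code{"first_10_weeks"}, \code{"none"}.
#' @return Score(s) in \{0, 0.5, 1\}.
#' @export
score_folic_acid <- function(category) {
  map <- c(periconceptional = 1, first_10_weeks = 0.5, none = 0)
  bad <- setdiff(unique(as.character(category)), names(map))
  if (length(bad) || anyNA(category))
    stop("unknown folic-acid category: ",
         paste(c(bad, if (anyNA(category)) "NA"), collapse = ", "))
  unname(map[as.character(category)])
}

check_amounts <- function(intake, cutoff) {
  if (anyNA(intake) || any(intake < 0))
    stop("intake must be non-negative and non-missing")
  if (anyNA(cutoff) || any(cutoff <= 0))
    stop("cutoff must be positive")
  invisible(NULL)
}

#' Compute the 15-component pregnancy diet-quality score
#'
#' Dispatches each registry component to its scoring rule and sums the
#' component scores into a total in \[0, 15\]; higher is healthier.
#'
#' @param record a one-row data frame or named list with one column per
#'   non-ratio component (intake in the registry unit), the two ratio
#'   columns \code{grain_quality_ratio} and \code{soft_fat_ratio},
#'   \code{alcohol_any} (logical or 0/1) and \code{folic_acid} (category
#'   string). Missing components are an error, never a silent zero.
#' @param registry component registry; defaults to [default_registry()].
#' @return A list of class \code{"diet_score"} with elements
#'   \code{component_scores} (named numeric, each in \[0, 1\]) and
#'   \code{total}.
#' @examples
#' rec <- list(vegetables = 250, fruit = 120, whole_grains = 90,
#'             legumes = 135, nuts = 15, dairy = 300, fish = 100, tea = 450,
#'             grain_quality_ratio = 0.5, soft_fat_ratio = 0.5,
#'             red_meat = 300, sugary_beverages = 0, salt = 5,
#'             alcohol_any = FALSE, folic_acid = "periconceptional")
#' score_pregnancy_diet(rec)$total
#' @export
score_pregnancy_diet <- function(record, registry = default_registry()) {
  validate_registry(registry)
  record <- as.list(record)
  missing <- setdiff(registry$name, names(record))
  # alcohol/folic intake columns carry their own names in the record
  missing <- setdiff(missing, c("alcohol", "folic_acid"))
  if (!("alcohol_any" %in% names(record))) missing <- c(missing, "alcohol_any")
  if (!("folic_acid" %in% names(record))) missing <- c(missing, "folic_acid")
  if (length(missing))
    stop("record is missing component value(s): ",
         paste(missing, collapse = ", "))

  scores <- numeric(nrow(registry))
  names(scores) <- registry$name
  for (i in seq_len(nrow(registry))) {
    nm <- registry$name[i]
    scores[i] <- switch(registry$kind[i],
      adequacy   = score_adequacy_component(record[[nm]], registry$cutoff[i]),
      moderation = score_moderation_component(record[[nm]], registry$cutoff[i]),
      ratio      = score_ratio_component(record[[nm]]),
      binary     = score_alcohol(as.logical(record[["alcohol_any"]])),
      categorical = score_folic_acid(record[["folic_acid"]])
    )
  }
  structure(list(component_scores = scores, total = sum(scores)),
            class = "diet_score")
}

#' @export
print.diet_score <- function(x, ...) {
  cat("Pregnancy diet-quality score:", round(x$total, 1), "of",
      length(x$component_scores), "\n")
  print(round(x$component_scores, 3))
  invisible(x)
}

#' Leave-one-component-out diet score
#'
#' Recomputes the diet-quality score over the remaining 14 components and
#' returns the excluded component's raw intake, for use as an extra model
#' covariate in leave-one-out sensitivity analyses.
#'
#' @inheritParams score_pregnancy_diet
#' @param excluded name of the component to drop.
#' @return A list with \code{score} (a \code{diet_score} over 14
#'   components, total in \[0, 14\]), \code{excluded} and
#'   \code{excluded_intake} (the raw record value; the component score for
#'   alcohol/folic acid, which have no continuous intake).
#' @export
score_excluding_component <- function(record, registry = default_registry(),
                                      excluded) {
  if (!excluded %in% registry$name)
    stop("unknown component: ", excluded)
  full <- score_pregnancy_diet(record, registry)
  sub <- score_pregnancy_diet(record, registry[registry$name != excluded, ])
  record <- as.list(record)
  raw <- switch(excluded,
                alcohol = full$component_scores[["alcohol"]],
                folic_acid = full$component_scores[["folic_acid"]],
                record[[excluded]])
  list(score = sub, excluded = excluded, excluded_intake = raw)
}

#' Score a table of maternal intake records
#'
#' Vectorised scoring of a whole intake table (one row per mother), the
#' form produced by [generate_cohort()] or read from a delimited intake
#' file with columns named after the registry components plus
#' \code{alcohol_any} (0/1 or logical) and \code{folic_acid}.
#'
#' @param table data frame of intake records; an \code{id} column is
#'   carried through if present.
#' @inheritParams score_pregnancy_diet
#' @return Data frame with one row per mother: \code{id} (if supplied),
#'   one column per component score, and \code{diet_score} (the total).
#' @export
score_intake_table <- function(table, registry = default_registry()) {
  validate_registry(registry)
  need <- c(setdiff(registry$name, c("alcohol", "folic_acid")),
            "alcohol_any", "folic_acid")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("intake table is missing column(s): ", paste(missing, collapse = ", "))

  out <- data.frame(row.names = seq_len(nrow(table)))
  if ("id" %in% names(table)) out$id <- table$id
  for (i in seq_len(nrow(registry))) {
    nm <- registry$name[i]
    out[[paste0("score_", nm)]] <- switch(registry$kind[i],
      adequacy   = score_adequacy_component(table[[nm]], registry$cutoff[i]),
      moderation = score_moderation_component(table[[nm]], registry$cutoff[i]),
      ratio      = score_ratio_component(table[[nm]]),
      binary     = score_alcohol(as.logical(table[["alcohol_any"]])),
      categorical = score_folic_acid(table[["folic_acid"]])
    )
  }
  out$diet_score <- rowSums(out[paste0("score_", registry$name)])
  out
}
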