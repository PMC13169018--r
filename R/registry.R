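#' Default food-component registry for the pregnancy diet-quality score
#'
#' The score sums 15 component scores, each in \[0, 1\]: eight adequacy
#' components rewarded up to a recommended minimum intake (vegetables,
#' fruit, whole grains, legumes, nuts, dairy, fish, tea), two dietary-ratio
#' components scored as the ratio itself (grain quality = whole grains /
#' total grains; soft fats and oils as a fraction of total fat), three
#' reverse-coded moderation components (red meat, sugar-containing
#' beverages, salt), a binary alcohol component and a three-level
#' folic-acid supplement component.
#'
#' Weekly-unit components (legumes, fish, red meat) are scored in grams per
#' week without conversion; the table reader enforces the unit labels
#' recorded here. A machine-readable copy ships as
#' \code{system.file("extdata", "diet_registry.json", package = "dietiq")}.
#'
#' @return A data frame with one row per component and columns
#'   \code{name}, \code{kind} (\code{"adequacy"}, \code{"moderation"},
#'   \code{"ratio"}, \code{"binary"} or \code{"categorical"}),
#'   \code{cutoff} (numeric; 1 for ratio kinds, NA for alcohol/folic acid)
#'   and \code{unit}.
#' @examples
#' default_registry()
#' @export
default_registry <- function() {
  reg <- data.frame(
    name = c("vegetables", "fruit", "whole_grains", "legumes", "nuts",
             "dairy", "fish", "tea", "grain_quality_ratio", "soft_fat_ratio",
             "red_meat", "sugary_beverages", "alcohol", "salt", "folic_acid"),
    kind = c(rep("adequacy", 8), "ratio", "ratio",
             "moderation", "moderation", "binary", "moderation", "categorical"),
    cutoff = c(200, 200, 90, 135, 15, 300, 100, 450, 1, 1, 375, 150, NA, 6, NA),
    unit = c("g/d", "g/d", "g/d", "g/w", "g/d", "g/d", "g/w", "g/d",
             "ratio", "ratio", "g/w", "g/d", "any", "g/d", "category"),
    stringsAsFactors = FALSE
  )
  validate_registry(reg)
  reg
}

#' Validate a component registry
#'
#' Checks the structural invariants: unique names, known kinds, positive
#' cut-offs for adequacy/moderation components and cutoff 1 for ratio
#' components.
#'
#' @param registry a data frame as returned by [default_registry()].
#' @return The registry, invisibly, if valid; otherwise an error.
#' @export
validate_registry <- function(registry) {
  stopifnot(is.data.frame(registry),
            all(c("name", "kind", "cutoff", "unit") %in% names(registry)))
  if (anyDuplicated(registry$name))
    stop("registry component names must be unique")
  bad_kind <- setdiff(registry$kind,
                      c("adequacy", "moderation", "ratio", "binary", "categorical"))
  if (length(bad_kind))
    stop("unknown component kind(s): ", paste(bad_kind, collapse = ", "))
  am <- registry$kind %in% c("adequacy", "moderation")
  if (any(!is.finite(registry$cutoff[am])) || any(registry$cutoff[am] <= 0))
    stop("adequacy/moderation components need a positive cutoff")
  if (any(registry$cutoff[registry$kind == "ratio"] != 1))
    stop("ratio components must have cutoff 1")
  invisible(registry)
}

#' Read a component registry from a JSON file
#'
#' @param path path to a JSON registry (array of objects with fields
#'   \code{name}, \code{kind}, \code{cutoff}, \code{unit}).
#' @return A validated registry data frame.
#' @export
read_registry <- function(path) {
  reg <- jsonlite::fromJSON(path)
  reg$cutoff <- as.numeric(reg$cutoff)
  validate_registry(reg)
  reg
}
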