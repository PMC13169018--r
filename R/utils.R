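# Internal helpers shared across modules.

# Run code with a local RNG state: seeds deterministically if `seed` is
# non-NULL, and always restores the caller's .Random.seed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (!is.null(seed)) set.seed(seed)
  code
}

# Derive a stage seed from a global seed; stays inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483587)
}

# Sample skewness (Fisher-Pearson, biased form); used by describe_cohort.
skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

`%||%` <- function(a, b) if (is.null(a)) b else a
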