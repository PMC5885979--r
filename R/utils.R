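# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched. `seed = NULL` means use the current RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; keeps results < 2^31.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(k) %% 100000L
}

# Round half away from zero (counts are non-negative here, so half-up).
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Signal a defined method failure (e.g. RLE on a table with no common
# feature) distinguishable from unexpected errors; the CLI maps it to a
# dedicated exit code.
defined_failure <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("gmprnorm_defined_failure", "error")))
}
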