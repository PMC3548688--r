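# Internal helpers shared across modules.

# Run code with a local RNG state seeded by `seed`; the caller's RNG stream is
# untouched. All randomised operations in the package go through this.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Full-precision number formatting for serialisation round trips.
fmt_num <- function(x) {
  vapply(x, function(v) formatC(v, format = "g", digits = 17), character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

NUMERIC_OPS <- c("<", ">", "<=", ">=")
CATEGORICAL_OPS <- c("==", "!=")

stop_fdx <- function(...) stop(sprintf(...), call. = FALSE)
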