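# Small shared helpers.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and then restores the caller's RNG
#' state, so package functions that take a `seed` argument are reproducible
#' without clobbering the user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive k reproducible sub-seeds (< 2^31) from one master seed.
.spawn_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max, k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
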