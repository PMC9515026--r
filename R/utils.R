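# Internal helpers: seeded evaluation without touching global RNG state,
# and deterministic fan-out of one user seed into per-purpose substreams.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's random stream. A `NULL` seed evaluates the expression with the
#' current stream (and does advance it).
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Derive a deterministic 31-bit subseed from a base seed and a stream label
#' @noRd
subseed <- function(seed, label, index = 0L) {
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(as.numeric(seed)) * 2654435761 + h * 97 + as.numeric(index)) %% 2147483629) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) if (!isTRUE(cond)) stopf(...)
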