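# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. `seed = NULL` means: use the current stream as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

check_binary_matrix <- function(Y, name = "Y") {
  Y <- as.matrix(Y)
  if (!is.numeric(Y)) stop(sprintf("`%s` must be a numeric 0/1 matrix", name))
  if (anyNA(Y) || !all(Y == 0 | Y == 1))
    stop(sprintf("`%s` must contain only 0 and 1", name))
  storage.mode(Y) <- "double"
  Y
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
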