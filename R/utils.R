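# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a string key
#'
#' One master seed governs a whole analysis; each randomised sub-step
#' (per-variable permutation tests, bootstrap cycles, random
#' reconstructions) draws its own child seed deterministically so that
#' adding or reordering sub-steps does not perturb the others.
#'
#' @param master integer master seed.
#' @param key character label of the sub-step.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.double(master %% m)
  for (ch in utf8ToInt(paste(key, collapse = "/"))) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Weighted mean/sd with total weight normalisation.
wmean <- function(x, w) sum(w * x) / sum(w)

# Stable order of distances with ties broken by id order.
stable_order <- function(d, ids) order(d, ids, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a
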