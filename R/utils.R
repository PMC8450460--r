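# Internal helpers: seeded evaluation and seed derivation.

# Evaluate expr under a local RNG seed, restoring global RNG state after.
# seed = NULL evaluates expr with the ambient RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer or NULL", call. = FALSE)
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

# Counter-based seed splitting: replicate/stage seeds derived from a master
# seed so that any single replicate can be re-run in isolation.  The rule
# (recorded in run manifests) is: seed_i = draw i of sample.int(2^31 - 2)
# under set.seed(master_seed + stream).
derive_seeds <- function(master_seed, n, stream = 0L) {
  if (is.null(master_seed)) return(rep(list(NULL), n))
  s <- with_seed(as.integer(master_seed) + as.integer(stream),
                 sample.int(2147483646L, n))
  as.list(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

stop_cfg <- function(...) stop(..., call. = FALSE)
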