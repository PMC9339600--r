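# Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the RNG stream as-is" (callers embedded in a seeded
# run consume the global stream so that a single set.seed() governs a run).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_param <- function(param, msg) {
  stop(sprintf("invalid parameter `%s`: %s", param, msg), call. = FALSE)
}

# Sparse adjacency (dgCMatrix, 0/1) of an undirected layer graph.
layer_adjacency <- function(g) {
  a <- igraph::as_adjacency_matrix(g, type = "both", sparse = TRUE)
  methods::as(a, "dMatrix")
}
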