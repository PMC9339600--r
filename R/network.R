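# Layer graphs, interlayer coupling and node influence.
#
# Layers are static undirected igraph objects without self-loops. The
# structural part of a node's influence is degree centrality times
# eigenvector centrality; the attribute part depends on its current carrier
# role (spreader / variation / oyster).

#' Generate a Barabasi-Albert scale-free layer graph
#'
#' Preferential-attachment graph used for both the online Internet layer and
#' (by default) the offline entity layer. Each new node attaches `m` edges to
#' existing nodes with probability proportional to their degree, giving a
#' connected scale-free graph with mean degree close to `2 m`.
#'
#' @param n number of nodes (must exceed `m`).
#' @param m edges added per new node (`>= 1`).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   consumed (so a surrounding `set.seed()` governs the draw).
#' @return an undirected, connected `igraph` graph with `n` vertices.
#' @examples
#' g <- build_ba_network(200, 5, seed = 1)
#' mean(igraph::degree(g))
#' @export
build_ba_network <- function(n, m, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) stop_param("n", "need an integer >= 2")
  if (!is.numeric(m) || length(m) != 1L || m < 1) stop_param("m", "need an integer >= 1")
  if (n <= m) stop_param("n", sprintf("node count n (%d) must exceed attachment parameter m (%d)", n, m))
  with_seed(seed, {
    igraph::sample_pa(n, power = 1, m = m, directed = FALSE, algorithm = "psumtree")
  })
}

#' Couple two layer graphs through a one-to-one node mapping
#'
#' Builds the two-layer coupled network: every online node has exactly one
#' offline counterpart. Three interlayer link modes are supported:
#' `"assortative"` matches nodes by degree rank (i-th highest-degree online
#' node to i-th highest-degree offline node), `"disassortative"` matches
#' highest to lowest, and `"random"` uses a seeded uniform permutation.
#' Degree ties are broken by ascending node id so every mode is deterministic
#' given the seed.
#'
#' @param online,offline undirected `igraph` layer graphs with equal node
#'   counts.
#' @param mode coupling mode, one of `"random"`, `"assortative"`,
#'   `"disassortative"`.
#' @param seed optional seed for the random mode.
#' @return an object of class `coupled_network`: list with elements `online`,
#'   `offline`, `mapping` (integer vector, `mapping[i]` is the offline
#'   counterpart of online node `i`) and `mode`.
#' @examples
#' s <- igraph::make_star(6, mode = "undirected")
#' couple_layers(s, s, mode = "assortative")$mapping[1]  # hub maps to hub
#' @export
couple_layers <- function(online, offline,
                          mode = c("random", "assortative", "disassortative"),
                          seed = NULL) {
  mode <- match.arg(mode)
  n <- igraph::vcount(online)
  if (igraph::vcount(offline) != n)
    stop_param("offline", sprintf("layer sizes differ (online %d, offline %d)",
                                  n, igraph::vcount(offline)))
  mapping <- switch(mode,
    random = with_seed(seed, sample.int(n)),
    assortative = {
      on_rank <- order(-igraph::degree(online), seq_len(n))
      off_rank <- order(-igraph::degree(offline), seq_len(n))
      mapping <- integer(n); mapping[on_rank] <- off_rank; mapping
    },
    disassortative = {
      on_rank <- order(-igraph::degree(online), seq_len(n))
      off_rank <- order(igraph::degree(offline), seq_len(n))
      mapping <- integer(n); mapping[on_rank] <- off_rank; mapping
    })
  structure(list(online = online, offline = offline,
                 mapping = mapping, mode = mode),
            class = "coupled_network")
}

#' @export
print.coupled_network <- function(x, ...) {
  cat(sprintf("<coupled_network> %d nodes/layer, %s interlayer links\n",
              igraph::vcount(x$online), x$mode))
  cat(sprintf("  online:  %d edges\n  offline: %d edges\n",
              igraph::ecount(x$online), igraph::ecount(x$offline)))
  invisible(x)
}

#' Degree centrality
#'
#' Degree of each node divided by `n - 1`, i.e. the fraction of the other
#' nodes it is adjacent to.
#'
#' @param g an `igraph` layer graph with at least two nodes.
#' @param v optional node id(s); default all nodes.
#' @return numeric vector of values in `[0, 1]`.
#' @examples
#' degree_centrality(igraph::make_full_graph(5))  # all 1
#' @export
degree_centrality <- function(g, v = NULL) {
  n <- igraph::vcount(g)
  if (n < 2) stop_param("g", "degree centrality needs at least 2 nodes")
  if (is.null(v)) v <- igraph::V(g)
  igraph::degree(g, v = v) / (n - 1)
}

#' Eigenvector centrality by power iteration
#'
#' Dominant eigenvector of the 0/1 adjacency matrix, computed by power
#' iteration and normalized to unit Euclidean norm. The result `x` satisfies
#' the fixed-point relation `A x = lambda_max x`; only the *relative*
#' magnitudes matter downstream (they enter influence ratios), which is why
#' the normalization constant is free and fixed here by convention.
#'
#' On an edgeless graph the centrality is identically zero and a warning is
#' raised; on disconnected graphs components not carrying the dominant
#' eigenvalue receive (numerically) zero centrality, which downstream code
#' guards against when dividing by summed influence.
#'
#' @param g an `igraph` layer graph.
#' @param tol convergence tolerance on the iterate change (default `1e-10`).
#' @param max_iter maximum number of iterations (default `10000`).
#' @return numeric vector of nonnegative centralities with unit Euclidean
#'   norm (all zeros for an edgeless graph).
#' @examples
#' ec <- eigen_centrality_power(igraph::make_star(10, mode = "undirected"))
#' ec[1] / ec[2]  # hub-to-leaf ratio equals sqrt(9) = 3
#' @export
eigen_centrality_power <- function(g, tol = 1e-10, max_iter = 10000L) {
  n <- igraph::vcount(g)
  if (n == 0) stop_param("g", "empty graph")
  if (igraph::ecount(g) == 0) {
    warning("graph has no edges; eigenvector centrality is identically zero")
    return(numeric(n))
  }
  a <- layer_adjacency(g)
  x <- rep(1 / sqrt(n), n)
  # iterate on (A + I): same eigenvectors, but the dominant eigenvalue is
  # strictly largest in magnitude even on bipartite graphs (where A itself
  # has -lambda_max in its spectrum and plain iteration oscillates)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(a %*% x) + x
    ny <- sqrt(sum(y^2))
    if (ny == 0) {  # defensive; cannot happen with edges and positive start
      warning("power iteration collapsed to the zero vector")
      return(numeric(n))
    }
    y <- y / ny
    if (max(abs(y - x)) < tol) return(pmax(y, 0))
    x <- y
  }
  warning("power iteration did not converge within max_iter; returning last iterate")
  pmax(x, 0)
}

#' Attribute influence of a carrier role
#'
#' Carrier roles carry different attribute weights: spreaders `alpha_s`,
#' variations `alpha_v` (a distorted rumor spreads more aggressively) and
#' oysters `alpha_o` (silent carriers exert less pull). Non-carrier states
#' have no attribute influence and raise an error.
#'
#' @param state character vector of carrier state labels (`"S"`, `"V"`, `"O"`).
#' @param config a [sim_config()] supplying `alpha_s`, `alpha_v`, `alpha_o`.
#' @return numeric vector of attribute weights.
#' @examples
#' attribute_influence(c("S", "V", "O"))
#' @export
attribute_influence <- function(state, config = sim_config()) {
  if (!all(is_carrier(state)))
    stop_param("state", "attribute influence is defined for carrier states S, V, O only")
  unname(c(S = config$alpha_s, V = config$alpha_v, O = config$alpha_o)[state])
}

#' Combined influence of a carrier node
#'
#' Product of degree centrality, eigenvector centrality and the attribute
#' influence of the node's current carrier role. The structural factors are
#' static over a run; only the attribute factor changes with the role.
#'
#' @param g an `igraph` layer graph.
#' @param v node id(s).
#' @param state carrier state label(s) for `v` (recycled if length 1).
#' @param config a [sim_config()].
#' @param ec optional precomputed [eigen_centrality_power()] vector for `g`.
#' @return a data.frame of class `influence_breakdown` with columns
#'   `node`, `DE`, `EC`, `Ar` and `influence` (`= DE * EC * Ar`).
#' @examples
#' g <- igraph::make_full_graph(4)
#' node_influence(g, 1:4, "S")
#' @export
node_influence <- function(g, v, state, config = sim_config(), ec = NULL) {
  if (is.null(ec)) ec <- eigen_centrality_power(g)
  state <- rep_len(state, length(v))
  de <- degree_centrality(g, v)
  ar <- attribute_influence(state, config)
  out <- data.frame(node = as.integer(v), DE = as.numeric(de),
                    EC = ec[as.integer(v)], Ar = ar)
  out$influence <- out$DE * out$EC * out$Ar
  class(out) <- c("influence_breakdown", class(out))
  out
}
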