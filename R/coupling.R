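# Offline-probability masking and social-reinforcement synchronization.
#
# The online Internet layer is only partially active at any step: each node
# is offline with probability `o` and then neither sends nor receives any
# in-layer influence. The cognitive transition between layers is a random
# state synchronization whose probability grows with the social-reinforcement
# count n (same-state neighbours around the target node).

#' Sample the per-step offline mask of the online layer
#'
#' i.i.d. Bernoulli(`o`) indicators, redrawn every step. Masked nodes do not
#' participate in in-layer information transmission that step: they are
#' excluded from neighbourhood counts and opinion means and make no state
#' transitions.
#'
#' @param o offline probability in `[0, 1]`.
#' @param n number of nodes.
#' @param seed optional seed.
#' @return logical vector of length `n` (`TRUE` = offline this step).
#' @examples
#' mean(sample_offline(0.97, 2000, seed = 1))
#' @export
sample_offline <- function(o, n, seed = NULL) {
  if (!is.numeric(o) || length(o) != 1L || is.na(o) || o < 0 || o > 1)
    stop_param("o", "offline probability must lie in [0, 1]")
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop_param("n", "need n >= 1")
  with_seed(seed, stats::runif(as.integer(n)) < o)
}

#' Social-reinforcement synchronization probability
#'
#' Probability that a node's state copies to its cross-layer counterpart,
#' given `n_same` same-state neighbours around the target:
#' `omega(n) = xi * n / (1 + gamma * n)`. The curve is zero at `n = 0`,
#' monotone non-decreasing, and saturates strictly below `xi / gamma`. For
#' large `xi` the raw value can exceed 1, in which case it is capped with a
#' warning.
#'
#' @param n_same nonnegative integer count(s) of same-state neighbours.
#' @param xi random state synchronization parameter, `>= 0`.
#' @param gamma social reinforcement parameter in `(0, 1)`.
#' @return probabilities in `[0, 1]`.
#' @examples
#' sync_probability(1)            # 0.1 / 1.2
#' sync_probability(0:5, xi = 0.4)
#' @export
sync_probability <- function(n_same, xi = 0.1, gamma = 0.2) {
  if (!is.numeric(xi) || length(xi) != 1L || is.na(xi) || xi < 0)
    stop_param("xi", "synchronization parameter must be >= 0")
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma <= 0 || gamma >= 1)
    stop_param("gamma", "reinforcement parameter must lie in (0, 1)")
  if (any(n_same < 0) || any(n_same != floor(n_same)))
    stop_param("n_same", "counts must be nonnegative integers")
  p <- xi * n_same / (1 + gamma * n_same)
  if (any(p > 1)) {
    warning("synchronization probability exceeded 1 and was capped")
    p <- pmin(p, 1)
  }
  p
}

#' Synchronize states from one layer onto the other
#'
#' For each source node `i` with counterpart `j` in the target layer,
#' `n_same` counts `j`'s neighbours (in the target layer) whose state equals
#' `state(i)`; carrier sub-roles are matched exactly, not pooled. With
#' probability [sync_probability()]`(n_same)` the target adopts the source
#' state; the opinion is copied along when the copied state is a carrier
#' state. Recovered targets are never overwritten (recovery is absorbing) and
#' an ignorant source exerts no synchronizing pressure (no-op).
#'
#' @param target_graph the target layer (`igraph` or sparse adjacency).
#' @param mapping integer vector: `mapping[i]` is the target counterpart of
#'   source node `i`.
#' @param source_states,target_states state label vectors of the two layers.
#' @param source_opinions,target_opinions opinion vectors (`NA` for nodes
#'   without an opinion).
#' @param xi,gamma see [sync_probability()].
#' @param u optional uniform variates (length = number of source nodes) for
#'   deterministic replay; drawn internally when `NULL`.
#' @return list with updated `states`, `opinions` (target layer) and the
#'   logical vector `synced` of synchronization events.
#' @examples
#' s <- igraph::make_star(5, mode = "undirected")
#' synchronize_states(s, 1:5, c("S", "I", "I", "I", "I"),
#'                    rep("I", 5), c(0.5, NA, NA, NA, NA), rep(NA_real_, 5),
#'                    u = rep(0, 5))
#' @export
synchronize_states <- function(target_graph, mapping, source_states, target_states,
                               source_opinions, target_opinions,
                               xi = 0.1, gamma = 0.2, u = NULL) {
  adj <- if (inherits(target_graph, "Matrix")) target_graph else layer_adjacency(target_graph)
  n <- length(source_states)
  stopifnot(length(mapping) == n, length(target_states) == nrow(adj))
  if (is.null(u)) u <- stats::runif(n)
  src <- .state_code(source_states)
  tgt <- .state_code(target_states)
  # per-state neighbour counts in the target layer (one sparse product per state)
  cnt <- vapply(1:5, function(k) as.numeric(adj %*% (tgt == k)), numeric(nrow(adj)))
  n_same <- cnt[cbind(mapping, src)]
  # large xi can push the raw reinforcement curve above 1; cap silently here
  # (the scalar sync_probability() warns, which would flood a full run)
  p <- pmin(suppressWarnings(sync_probability(n_same, xi = xi, gamma = gamma)), 1)
  synced <- u < p & src != .CODE_I & tgt[mapping] != .CODE_R & src != tgt[mapping]
  new_states <- tgt
  new_opinions <- target_opinions
  if (any(synced)) {
    j <- mapping[synced]
    new_states[j] <- src[synced]
    carrier_copy <- .is_carrier_code(src[synced])
    new_opinions[j[carrier_copy]] <- source_opinions[which(synced)[carrier_copy]]
  }
  list(states = .state_label(new_states), opinions = new_opinions, synced = synced)
}
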