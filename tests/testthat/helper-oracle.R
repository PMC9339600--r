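# Independent brute-force oracles used to cross-check the implementation.
# Everything here is written straight from the model's defining formulas,
# per node, without reusing the package's vectorized code paths.

# Dominant eigenvector of the adjacency matrix via full dense
# eigendecomposition (unit Euclidean norm, nonnegative orientation).
dense_eigen_centrality <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  e <- eigen(a, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- v / sqrt(sum(v^2))
  if (sum(v) < 0) v <- -v
  pmax(v, 0)
}

# Mean of a Normal(mean, sd) truncated to [0, 1], by numerical integration.
truncnorm_mean_quadrature <- function(mean, sd) {
  z <- stats::integrate(function(x) stats::dnorm(x, mean, sd), 0, 1)$value
  m1 <- stats::integrate(function(x) x * stats::dnorm(x, mean, sd), 0, 1)$value
  m1 / z
}

# ---------------------------------------------------------------------------
# Straight-line per-node replay of one synchronous step from a randomness
# tape. Reads only the public pieces of a sim_state (graphs, mapping,
# thresholds, states, opinions, config); structural influence is recomputed
# from scratch with the dense eigensolver.
oracle_step <- function(state, tape) {
  cfg <- state$config
  n <- cfg$n
  layers <- c("online", "offline")
  nbrs <- lapply(layers, function(l)
    lapply(seq_len(n), function(i)
      as.integer(igraph::neighbors(state$net[[l]], i))))
  names(nbrs) <- layers
  w <- lapply(layers, function(l)
    (igraph::degree(state$net[[l]]) / (n - 1)) * dense_eigen_centrality(state$net[[l]]))
  names(w) <- layers
  alpha <- c(S = cfg$alpha_s, V = cfg$alpha_v, O = cfg$alpha_o)
  carrier <- function(s) s %in% c("S", "V", "O")
  t_new <- state$t + 1L

  st <- lapply(state$states, function(s) .state_label_oracle(s))
  op <- state$opinions

  # (1) offline mask
  p_off <- if (cfg$invert_offline) 1 - cfg$offline_prob else cfg$offline_prob
  mask <- tape$mask < p_off
  active <- list(online = !mask, offline = rep(TRUE, n))

  # (2) synchronization, computed from the pre-sync snapshot of both layers
  if (cfg$xi > 0) {
    snap <- st
    apply_sync <- function(src_layer, tgt_layer, map, u) {
      new_st <- st[[tgt_layer]]
      new_op <- op[[tgt_layer]]
      for (i in seq_len(n)) {
        s_src <- snap[[src_layer]][i]
        if (s_src == "I") next
        j <- map[i]
        if (snap[[tgt_layer]][j] == "R") next
        if (snap[[tgt_layer]][j] == s_src) next  # same state: vacuous sync
        n_same <- sum(snap[[tgt_layer]][nbrs[[tgt_layer]][[j]]] == s_src)
        p <- cfg$xi * n_same / (1 + cfg$reinforcement * n_same)
        if (u[i] < min(p, 1)) {
          new_st[j] <- s_src
          if (carrier(s_src)) new_op[j] <- op[[src_layer]][i]
        }
      }
      list(st = new_st, op = new_op)
    }
    fwd <- apply_sync("online", "offline", state$mapping, tape$sync)
    if (cfg$sync_direction == "bidirectional") {
      bwd <- apply_sync("offline", "online", order(state$mapping), tape$sync_back)
      st$online <- bwd$st; op$online <- bwd$op
    }
    st$offline <- fwd$st; op$offline <- fwd$op
  }

  # (3)-(7) intra-layer dynamics, per node, from the post-sync snapshot
  for (l in layers) {
    s0 <- st[[l]]; x0 <- op[[l]]
    s1 <- s0; x1 <- x0
    for (i in seq_len(n)) {
      nb <- nbrs[[l]][[i]]
      part <- nb[active[[l]][nb]]
      denom <- length(part)
      n_carrier <- sum(carrier(s0[part]))
      frac <- if (denom > 0) n_carrier / denom else 0

      if (s0[i] == "I" && active[[l]][i]) {
        if (denom > 0 && frac >= state$phi[[l]][i]) {
          # newly aroused: role by influence-proportional intervals
          inf <- c(S = 0, V = 0, O = 0)
          for (nb_j in part) if (carrier(s0[nb_j]))
            inf[s0[nb_j]] <- inf[s0[nb_j]] + w[[l]][nb_j] * alpha[s0[nb_j]]
          tot <- sum(inf)
          r <- tape$role[[l]][i]
          role <- if (tot <= 0) "S"
                  else if (r < inf[["S"]] / tot) "S"
                  else if (r < (inf[["S"]] + inf[["V"]]) / tot) "V"
                  else "O"
          s1[i] <- role
          x1[i] <- oracle_init_opinion(role, cfg, tape$opin[[l]][i])
        } else if (cfg$ignorant_direct_immunity && t_new >= cfg$immune_start) {
          rec <- if (cfg$extinction_direction == "prose")
            frac < state$varphi[[l]][i] else frac >= state$varphi[[l]][i]
          if (rec) s1[i] <- "R"
        }
      } else if (carrier(s0[i]) && active[[l]][i]) {
        # bounded-confidence update against the participating carrier mean
        cn <- part[carrier(s0[part])]
        if (length(cn) > 0) {
          xbar <- sum(x0[cn]) / length(cn)
          delta <- abs(x0[i] - xbar)
          xi_new <- x0[i]
          if (delta < cfg$d1) xi_new <- x0[i] + cfg$mu * (xbar - x0[i])
          else if (delta > cfg$d2) xi_new <- x0[i] + cfg$mu * (x0[i] - xbar)
          xi_new <- min(max(xi_new, -1), 1)
          if (x0[i] >= 0 && x0[i] <= cfg$rho3) xi_new <- max(xi_new, x0[i])
          x1[i] <- xi_new
        }
        # reclassification from the updated opinion
        s1[i] <- oracle_classify(x1[i], cfg)
        # extinction gate
        if (t_new >= cfg$immune_start) {
          rec <- if (cfg$extinction_direction == "prose")
            frac < state$varphi[[l]][i] else frac >= state$varphi[[l]][i]
          if (rec) s1[i] <- "R"
        }
      }
    }
    st[[l]] <- s1; op[[l]] <- x1
  }
  list(states = st, opinions = op)
}

.state_label_oracle <- function(code) c("I", "S", "V", "O", "R")[code]

oracle_classify <- function(x, cfg) {
  if ((x >= 0 && x < cfg$rho3) || (x > cfg$rho4 && x <= 1)) "S"
  else if ((x >= -1 && x < cfg$rho1) || (x > cfg$rho2 && x < 0)) "V"
  else "O"
}

# Length-weighted inverse-CDF opinion draw on a role's interval union,
# mirroring the arithmetic of the documented contract.
oracle_init_opinion <- function(role, cfg, u) {
  eps <- 1e-9
  if (role == "S") {
    l1 <- cfg$rho3; l2 <- 1 - cfg$rho4
    s <- u * (l1 + l2)
    if (s < l1) { x <- 0 + s; if (x >= l1) x <- l1 - eps; x }
    else max(cfg$rho4 + (s - l1), cfg$rho4 + eps)
  } else if (role == "V") {
    l1 <- cfg$rho1 + 1; l2 <- -cfg$rho2
    s <- u * (l1 + l2)
    if (s < l1) { x <- -1 + s; if (x >= cfg$rho1) x <- cfg$rho1 - eps; x }
    else max(cfg$rho2 + (s - l1), cfg$rho2 + eps)
  } else {
    l1 <- cfg$rho2 - cfg$rho1; l2 <- cfg$rho4 - cfg$rho3
    s <- u * (l1 + l2)
    if (s < l1) cfg$rho1 + s else cfg$rho3 + (s - l1)
  }
}
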