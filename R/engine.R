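# Monte-Carlo engine: initialization, the synchronous per-step update, full
# runs and parameter sweeps.
#
# Per-step event order (all decisions read the state snapshot taken after
# interlayer synchronization; newly activated nodes do not transmit until
# the next step):
#   1. draw the offline mask of the online layer
#   2. interlayer state synchronization (online -> offline, optionally both)
#   3. arousal of ignorants (per layer)
#   4. carrier-role assignment of the newly aroused + opinion initialization
#   5. bounded-confidence opinion updates of existing carriers
#   6. opinion-based reclassification of carriers
#   7. extinction (carriers -> recovered, gated by the immunity-onset step)

.LAYERS <- c("online", "offline")

#' Initialize a simulation state
#'
#' Builds (or accepts) the two layer graphs, couples them, samples the static
#' per-node threshold traits, seeds the initial carriers and records the
#' densities at `t = 0`. All randomness is governed by `config$seed`, so the
#' same configuration always yields a bit-identical initial state.
#'
#' Initial carriers are seeded at counterpart pairs: the same uniformly
#' chosen nodes (and their offline counterparts) start as carriers in both
#' layers, each drawing its own initial opinion. Under the default
#' `initial_opinion = "uniform"` the opinion is drawn uniformly on
#' `[-1, 1]` and the starting role is classified from it; with
#' `"role_interval"` every seed starts as an ordinary spreader with an
#' opinion drawn from the spreader intervals.
#'
#' @param config a [sim_config()].
#' @param online,offline optional user-supplied layer graphs (`igraph`,
#'   node count equal to `config$n`); generated internally when `NULL`.
#' @return an object of class `sim_state`.
#' @examples
#' st <- initialize_sim(sim_config(n = 50, m = 2, horizon = 5))
#' st$t
#' @export
initialize_sim <- function(config, online = NULL, offline = NULL) {
  config <- validate_config(config)
  set.seed(config$seed)
  n <- config$n
  if (is.null(online)) online <- build_ba_network(n, config$m)
  if (is.null(offline)) {
    offline <- switch(config$offline_topology,
      ba = build_ba_network(n, config$m),
      ws = igraph::sample_smallworld(1, n, config$m, p = 0.1))
  }
  if (igraph::vcount(online) != n || igraph::vcount(offline) != n)
    stop_param("online", "supplied layer graphs must have config$n nodes")
  net <- couple_layers(online, offline, mode = config$coupling_mode)

  adj <- list(online = layer_adjacency(online), offline = layer_adjacency(offline))
  # static structural influence weight DE * EC per layer
  w <- lapply(.LAYERS, function(l) {
    g <- net[[l]]
    degree_centrality(g) * eigen_centrality_power(g)
  })
  names(w) <- .LAYERS
  phi <- list(online = sample_thresholds(config$phi_mean, config$phi_sd, n),
              offline = sample_thresholds(config$phi_mean, config$phi_sd, n))
  varphi <- list(online = sample_thresholds(config$varphi_mean, config$varphi_sd, n),
                 offline = sample_thresholds(config$varphi_mean, config$varphi_sd, n))

  states <- list(online = rep(.CODE_I, n), offline = rep(.CODE_I, n))
  opinions <- list(online = rep(NA_real_, n), offline = rep(NA_real_, n))
  k <- n_initial_carriers(config)
  rho <- silence_intervals(config$rho1, config$rho2, config$rho3, config$rho4)
  if (k > 0) {
    seeds_online <- sample.int(n, k)
    idx <- list(online = seeds_online, offline = net$mapping[seeds_online])
    for (l in .LAYERS) {
      if (config$initial_opinion == "uniform") {
        x <- stats::runif(k, -1, 1)
        states[[l]][idx[[l]]] <- classify_code(x, rho)
      } else {
        x <- initialize_opinion("S", rho, n = k)
        states[[l]][idx[[l]]] <- .CODE_S
      }
      opinions[[l]][idx[[l]]] <- x
    }
  }

  state <- structure(list(
    config = config, net = net, adj = adj, mapping = net$mapping,
    w = w, phi = phi, varphi = varphi,
    states = states, opinions = opinions,
    t = 0L, densities = list(), role_fallbacks = 0L,
    statelog = if (config$record_statelog) list() else NULL
  ), class = "sim_state")
  state$densities[[1]] <- .density_row(state)
  if (config$record_statelog) state$statelog[[1]] <- .statelog_rows(state)
  state
}

.density_row <- function(state) {
  n <- state$config$n
  out <- lapply(.LAYERS, function(l) {
    tab <- tabulate(state$states[[l]], nbins = 5L) / n
    c(I = tab[1], S = tab[2], V = tab[3], O = tab[4], R = tab[5])
  })
  names(out) <- .LAYERS
  out
}

.statelog_rows <- function(state) {
  n <- state$config$n
  do.call(rbind, lapply(.LAYERS, function(l) {
    data.frame(t = state$t, node = seq_len(n) - 1L, layer = l,
               state = .state_label(state$states[[l]]),
               opinion = state$opinions[[l]])
  }))
}

#' Draw the randomness tape for one step
#'
#' One step of the engine consumes fixed-length vectors of uniform variates
#' regardless of the current state: the offline-mask draws, the
#' synchronization draws (one per node and direction) and, per layer, one
#' role draw and one opinion-initialization draw per node. Keeping all
#' randomness on such a tape makes RNG consumption state-independent and
#' allows [sim_step()] to be replayed exactly against an external per-node
#' oracle.
#'
#' @param state a `sim_state`.
#' @return a named list of uniform vectors
#'   (`mask`, `sync`, `sync_back`, `role`, `opin`).
#' @export
draw_tape <- function(state) {
  n <- state$config$n
  bidir <- state$config$sync_direction == "bidirectional"
  list(mask = stats::runif(n),
       sync = stats::runif(n),
       sync_back = if (bidir) stats::runif(n) else NULL,
       role = list(online = stats::runif(n), offline = stats::runif(n)),
       opin = list(online = stats::runif(n), offline = stats::runif(n)))
}

# Intra-layer synchronous update (steps 3-7 of the event order).
# Returns list(states, opinions, fallbacks).
.intra_layer_step <- function(adj, states, opinions, phi, varphi, w, active,
                              t_new, cfg, rho, role_u, opin_u) {
  carrier <- .is_carrier_code(states)
  act <- as.numeric(active)
  num <- as.numeric(adj %*% (carrier * act))       # participating carrier neighbours
  den <- as.numeric(adj %*% act)                   # participating neighbours
  frac <- ifelse(den > 0, num / den, 0)

  # (3) arousal of ignorants
  new_idx <- which(states == .CODE_I & active & den > 0 & frac >= phi)

  # (4) role assignment by influence-proportional intervals + opinion init
  fallbacks <- 0L
  if (length(new_idx)) {
    inf_s <- cfg$alpha_s * as.numeric(adj %*% (w * (states == .CODE_S) * act))
    inf_v <- cfg$alpha_v * as.numeric(adj %*% (w * (states == .CODE_V) * act))
    inf_o <- cfg$alpha_o * as.numeric(adj %*% (w * (states == .CODE_O) * act))
    tot <- inf_s + inf_v + inf_o
    r <- role_u[new_idx]
    ts <- tot[new_idx]
    role <- rep(.CODE_S, length(new_idx))
    pos <- ts > 0
    fallbacks <- sum(!pos)
    role[pos & r >= inf_s[new_idx] / ts] <- .CODE_V
    role[pos & r >= (inf_s[new_idx] + inf_v[new_idx]) / ts] <- .CODE_O
    new_opin <- numeric(length(new_idx))
    for (k in c(.CODE_S, .CODE_V, .CODE_O)) {
      sel <- role == k
      if (any(sel))
        new_opin[sel] <- initialize_opinion(.state_label(k), rho, u = opin_u[new_idx][sel])
    }
  }

  # (5) opinion updates of existing carriers with participating carrier
  #     neighbours (neighbour mean over participating carriers only)
  op_fill <- ifelse(carrier & active & !is.na(opinions), opinions, 0)
  xbar_num <- as.numeric(adj %*% op_fill)
  upd <- which(carrier & active)
  if (length(upd)) {
    xbar <- ifelse(num[upd] > 0, xbar_num[upd] / num[upd], NA_real_)
    opinions[upd] <- opinion_update(opinions[upd], xbar, mu = cfg$mu,
                                    d1 = cfg$d1, d2 = cfg$d2, rho = rho,
                                    literal = cfg$literal_opinion_rule)
    # (6) opinion-based reclassification
    states[upd] <- classify_code(opinions[upd], rho)
  }

  # (7) extinction of snapshot carriers (participating only), gated by onset
  if (t_new >= cfg$immune_start) {
    cand <- which(carrier & active)
    if (length(cand)) {
      rec <- if (cfg$extinction_direction == "prose") frac[cand] < varphi[cand]
             else frac[cand] >= varphi[cand]
      states[cand[rec]] <- .CODE_R
    }
    if (cfg$ignorant_direct_immunity) {
      ig <- setdiff(which(states == .CODE_I & active), new_idx)
      if (length(ig)) {
        rec <- if (cfg$extinction_direction == "prose") frac[ig] < varphi[ig]
               else frac[ig] >= varphi[ig]
        states[ig[rec]] <- .CODE_R
      }
    }
  }

  if (length(new_idx)) {
    states[new_idx] <- role
    opinions[new_idx] <- new_opin
  }
  list(states = states, opinions = opinions, fallbacks = fallbacks)
}

#' Advance the simulation by one step
#'
#' Applies the per-step event order documented above synchronously: all
#' neighbourhood quantities are computed from the post-synchronization
#' snapshot, so newly activated nodes do not transmit until the next step.
#'
#' @param state a `sim_state` from [initialize_sim()] or a previous
#'   `sim_step()`.
#' @param tape optional randomness tape from [draw_tape()]; drawn internally
#'   when `NULL`.
#' @return the updated `sim_state` (with `t` advanced and densities appended).
#' @export
sim_step <- function(state, tape = NULL) {
  cfg <- state$config
  n <- cfg$n
  if (is.null(tape)) tape <- draw_tape(state)
  rho <- silence_intervals(cfg$rho1, cfg$rho2, cfg$rho3, cfg$rho4)
  t_new <- state$t + 1L

  # (1) offline mask of the online layer
  p_off <- if (cfg$invert_offline) 1 - cfg$offline_prob else cfg$offline_prob
  mask <- tape$mask < p_off
  active <- list(online = !mask, offline = rep(TRUE, n))

  # (2) interlayer synchronization (reads the pre-sync snapshot for both
  #     directions, then applies)
  st <- state$states
  op <- state$opinions
  if (cfg$xi > 0) {
    fwd <- synchronize_states(state$adj$offline, state$mapping,
                              .state_label(st$online), .state_label(st$offline),
                              op$online, op$offline,
                              xi = cfg$xi, gamma = cfg$reinforcement, u = tape$sync)
    if (cfg$sync_direction == "bidirectional") {
      inv_map <- order(state$mapping)   # offline j -> online counterpart
      bwd <- synchronize_states(state$adj$online, inv_map,
                                .state_label(st$offline), .state_label(st$online),
                                op$offline, op$online,
                                xi = cfg$xi, gamma = cfg$reinforcement,
                                u = tape$sync_back)
      st$online <- .state_code(bwd$states); op$online <- bwd$opinions
    }
    st$offline <- .state_code(fwd$states); op$offline <- fwd$opinions
  }

  # (3)-(7) intra-layer dynamics on the post-sync snapshot
  for (l in .LAYERS) {
    res <- .intra_layer_step(state$adj[[l]], st[[l]], op[[l]],
                             state$phi[[l]], state$varphi[[l]], state$w[[l]],
                             active[[l]], t_new, cfg, rho,
                             tape$role[[l]], tape$opin[[l]])
    st[[l]] <- res$states
    op[[l]] <- res$opinions
    state$role_fallbacks <- state$role_fallbacks + res$fallbacks
  }

  state$states <- st
  state$opinions <- op
  state$t <- t_new
  state$densities[[t_new + 1L]] <- .density_row(state)
  if (!is.null(state$statelog)) state$statelog[[t_new + 1L]] <- .statelog_rows(state)
  state
}

#' Extract the per-step, per-layer density time series
#'
#' @param state a `sim_state` (or a `sim_result` from [run_sim()]).
#' @return a data.frame with columns `t`, `layer`, `I`, `S`, `V`, `O`, `R`
#'   and the derived carrier density `C = S + V + O`, ordered by `(t, layer)`.
#' @export
sim_timeseries <- function(state) {
  if (inherits(state, "sim_result")) return(state$timeseries)
  rows <- lapply(seq_along(state$densities), function(i) {
    d <- state$densities[[i]]
    do.call(rbind, lapply(.LAYERS, function(l) {
      data.frame(t = i - 1L, layer = l, I = d[[l]][["I"]], S = d[[l]][["S"]],
                 V = d[[l]][["V"]], O = d[[l]][["O"]], R = d[[l]][["R"]])
    }))
  })
  out <- do.call(rbind, rows)
  out$C <- out$S + out$V + out$O
  out[order(out$t, match(out$layer, .LAYERS)), , drop = FALSE]
}

#' Summary statistics of a finished run
#'
#' Per layer: the peak carrier density `max C(t)` and the step at which it is
#' attained, the peak oyster density `max O(t)`, and the final recovered
#' density.
#'
#' @param x a `sim_result` from [run_sim()] or a timeseries data.frame from
#'   [sim_timeseries()].
#' @return a data.frame with one row per layer and columns `layer`,
#'   `peak_c`, `peak_c_time`, `peak_o`, `final_r`.
#' @export
run_summary <- function(x) {
  ts <- if (is.data.frame(x)) x else sim_timeseries(x)
  do.call(rbind, lapply(.LAYERS, function(l) {
    d <- ts[ts$layer == l, , drop = FALSE]
    data.frame(layer = l,
               peak_c = max(d$C), peak_c_time = d$t[which.max(d$C)],
               peak_o = max(d$O), final_r = d$R[nrow(d)])
  }))
}

#' Run a full seeded simulation
#'
#' Initializes from `config` (honouring `config$seed`) and advances
#' `config$horizon` steps.
#'
#' @param config a [sim_config()].
#' @param online,offline optional user-supplied layer graphs (see
#'   [initialize_sim()]).
#' @return an object of class `sim_result`: list with `timeseries` (see
#'   [sim_timeseries()]), `summary` (see [run_summary()]), `config`, the
#'   final `state`, and `statelog` (a data.frame, only when
#'   `config$record_statelog` is `TRUE`).
#' @examples
#' res <- run_sim(sim_config(n = 100, m = 3, horizon = 10, seed = 7))
#' head(res$timeseries)
#' @export
run_sim <- function(config, online = NULL, offline = NULL) {
  state <- initialize_sim(config, online = online, offline = offline)
  for (i in seq_len(config$horizon)) state <- sim_step(state)
  ts <- sim_timeseries(state)
  structure(list(timeseries = ts, summary = run_summary(ts),
                 config = config, state = state,
                 statelog = if (!is.null(state$statelog))
                   do.call(rbind, state$statelog) else NULL),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> n = %d, %d steps, seed = %d\n",
              x$config$n, x$config$horizon, x$config$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Parameter sweep with replicated seeded runs
#'
#' Repeats [run_sim()] for each value of one scalar configuration parameter,
#' with `replicates` independent seeds per value (derived deterministically
#' from `config$seed`), and returns the per-replicate summaries in tidy form.
#'
#' @param config the base [sim_config()].
#' @param param name of a scalar `sim_config` field (e.g. `"alpha_v"`).
#' @param values numeric vector of parameter values to sweep.
#' @param replicates replicated runs per value (default 20).
#' @return a tidy data.frame with columns `param`, `value`, `replicate`,
#'   `seed` and the [run_summary()] columns; aggregate with
#'   [summarize_sweep()].
#' @examples
#' sw <- sweep_sim(sim_config(n = 80, m = 2, horizon = 10),
#'                 "alpha_v", c(1.5, 2.5), replicates = 2)
#' summarize_sweep(sw)
#' @export
sweep_sim <- function(config, param, values, replicates = 20L) {
  if (!param %in% names(.config_fields()) ||
      !is.numeric(config[[param]]))
    stop_param("param", "must name a scalar numeric sim_config field")
  if (!is.numeric(values) || !length(values)) stop_param("values", "need numeric values")
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max,
                                             length(values) * replicates))
  rows <- list()
  k <- 0L
  for (vi in seq_along(values)) {
    for (ri in seq_len(replicates)) {
      k <- k + 1L
      over <- list(values[vi], seeds[k])
      names(over) <- c(param, "seed")
      cfg <- do.call(sim_config, utils::modifyList(unclass(config), over))
      sm <- run_sim(cfg)$summary
      sm <- cbind(data.frame(param = param, value = values[vi],
                             replicate = ri, seed = seeds[k]), sm)
      rows[[k]] <- sm
    }
  }
  do.call(rbind, rows)
}

#' @rdname sweep_sim
#' @param sweep a data.frame from `sweep_sim()`.
#' @return `summarize_sweep()`: one row per `(value, layer)` with the mean
#'   and standard deviation of each summary field.
#' @export
summarize_sweep <- function(sweep) {
  fields <- c("peak_c", "peak_c_time", "peak_o", "final_r")
  out <- list()
  for (v in unique(sweep$value)) for (l in unique(sweep$layer)) {
    d <- sweep[sweep$value == v & sweep$layer == l, , drop = FALSE]
    row <- data.frame(param = d$param[1], value = v, layer = l, n_replicates = nrow(d))
    for (f in fields) {
      row[[paste0(f, "_mean")]] <- mean(d[[f]])
      row[[paste0(f, "_sd")]] <- stats::sd(d[[f]])
    }
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}
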