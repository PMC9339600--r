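# Threshold-based activation/extinction and carrier-role assignment.
#
# Every node draws two static traits at initialization: an arousal threshold
# (minimum carrier fraction in its neighbourhood needed to wake an ignorant)
# and an extinguishing threshold (the neighbourhood condition that drives a
# carrier into the absorbing recovered state once immunity has set in).

#' Sample truncated-normal node thresholds
#'
#' Thresholds are i.i.d. Normal(`mean`, `sd`) draws truncated to `[0, 1]` by
#' rejection resampling, so the realized distribution is the conditional
#' normal on the unit interval (not a clipped normal). `sd = 0` yields the
#' degenerate distribution at `mean`.
#'
#' @param mean distribution mean (inside `[0, 1]` when `sd = 0`).
#' @param sd distribution standard deviation, `>= 0`.
#' @param n number of nodes.
#' @param seed optional seed.
#' @return numeric vector of `n` thresholds in `[0, 1]`.
#' @examples
#' range(sample_thresholds(0.2, 0.5, 1000, seed = 1))
#' @export
sample_thresholds <- function(mean, sd, n, seed = NULL) {
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0)
    stop_param("sd", "standard deviation must be >= 0")
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop_param("n", "need n >= 1")
  n <- as.integer(n)
  if (sd == 0) {
    if (mean < 0 || mean > 1)
      stop_param("mean", "degenerate threshold (sd = 0) must lie in [0, 1]")
    return(rep(mean, n))
  }
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      draw <- stats::rnorm(max(n - length(out), 16L) * 2L, mean, sd)
      out <- c(out, draw[draw >= 0 & draw <= 1])
    }
    out[seq_len(n)]
  })
}

#' Arousal decision for an ignorant node
#'
#' An ignorant node wakes up (becomes a carrier) when the fraction of rumor
#' carriers among its participating neighbours reaches its arousal threshold:
#' `carriers / neighbours >= threshold` (the boundary activates). A node with
#' no participating neighbours has no exposure and never activates.
#'
#' @param neighbor_states character vector of the states of the node's
#'   participating neighbours this step (offline-masked neighbours excluded).
#' @param threshold the node's arousal threshold in `[0, 1]`.
#' @return integer `1` (activate) or `0`.
#' @examples
#' arousal_decision(c("S", "S", "V", "I", "R"), 0.2)  # 3/5 >= 0.2 -> 1
#' @export
arousal_decision <- function(neighbor_states, threshold) {
  n_all <- length(neighbor_states)
  if (n_all == 0L) return(0L)
  frac <- sum(is_carrier(neighbor_states)) / n_all
  as.integer(frac >= threshold)
}

#' Extinguishing decision for a carrier
#'
#' Evaluated only from the immunity-onset step `immune_start` onwards; before
#' that no node can recover. With the default `"prose"` direction a carrier
#' recovers when the rumor energy around it has faded, i.e. when the carrier
#' fraction among its participating neighbours falls *below* its
#' extinguishing threshold (a node with no participating neighbours perceives
#' zero support and recovers). The `"as_printed"` direction implements the
#' opposite inequality (recover when the fraction is `>=` the threshold); see
#' the methods vignette for why both are exposed.
#'
#' @param neighbor_states states of participating neighbours (see
#'   [arousal_decision()]).
#' @param threshold the node's extinguishing threshold in `[0, 1]`.
#' @param t the time step being computed.
#' @param immune_start first step at which recovery is possible (default 15).
#' @param direction `"prose"` (default) or `"as_printed"`.
#' @return integer `1` (recover) or `0`.
#' @examples
#' extinguish_decision(c("I", "I", "I", "S"), 0.3, t = 20)  # 1/4 < 0.3 -> 1
#' extinguish_decision(c("S", "S"), 0.3, t = 10)            # gated -> 0
#' @export
extinguish_decision <- function(neighbor_states, threshold, t,
                                immune_start = 15,
                                direction = c("prose", "as_printed")) {
  direction <- match.arg(direction)
  if (t < immune_start) return(0L)
  n_all <- length(neighbor_states)
  frac <- if (n_all == 0L) 0 else sum(is_carrier(neighbor_states)) / n_all
  if (direction == "prose") as.integer(frac < threshold)
  else as.integer(frac >= threshold)
}

#' Assign a carrier role to a newly aroused node
#'
#' A node that has just been activated adopts the role S, V or O with
#' probability proportional to the summed influence of its activated
#' neighbours in that role: the unit interval is partitioned into
#' `[0, inf_S/inf_All)`, `[inf_S/inf_All, inf_{S+V}/inf_All)` and the
#' remainder, and the uniform draw `r` selects the role. When no activated
#' neighbour carries positive influence the partition is undefined and the
#' node falls back to the ordinary spreader role (with a warning).
#'
#' @param inf_s,inf_v,inf_o summed influence of neighbouring spreaders,
#'   variations and oysters (nonnegative).
#' @param r uniform draw in `[0, 1)`.
#' @return a state label: `"S"`, `"V"` or `"O"`.
#' @examples
#' assign_carrier_role(1, 1, 2, r = 0.30)  # 0.25 <= 0.30 < 0.50 -> "V"
#' @export
assign_carrier_role <- function(inf_s, inf_v, inf_o, r) {
  if (min(inf_s, inf_v, inf_o) < 0)
    stop_param("inf_s", "influence sums must be nonnegative")
  if (r < 0 || r >= 1) stop_param("r", "uniform draw must lie in [0, 1)")
  tot <- inf_s + inf_v + inf_o
  if (tot <= 0) {
    warning("all neighbour influences are zero; falling back to spreader role")
    return("S")
  }
  if (r < inf_s / tot) "S"
  else if (r < (inf_s + inf_v) / tot) "V"
  else "O"
}
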