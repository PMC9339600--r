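# Bounded-confidence opinion dynamics with silence intervals.
#
# Every carrier holds a continuous opinion x in [-1, 1]. Position in opinion
# space determines the carrier role: positive opinions outside the
# spreader-side silence interval are ordinary spreaders, negative opinions
# outside the variation-side silence interval are variations (distorted-rumor
# spreaders), and opinions inside either silence interval are oysters
# (silent, wait-and-see carriers).

#' Silence intervals of opinion space
#'
#' The four silence coefficients delimit the two oyster (silent) intervals:
#' `[rho1, rho2]` on the variation (negative) side and `[rho3, rho4]` on the
#' spreader (positive) side. They must satisfy
#' `-1 < rho1 < rho2 <= 0 <= rho3 < rho4 < 1`.
#'
#' @param rho1,rho2 variation-side bounds.
#' @param rho3,rho4 spreader-side bounds.
#' @return an object of class `silence_intervals`.
#' @examples
#' silence_intervals()
#' @export
silence_intervals <- function(rho1 = -0.4, rho2 = -0.2, rho3 = 0.2, rho4 = 0.3) {
  for (nm in c("rho1", "rho2", "rho3", "rho4")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) stop_param(nm, "need a single number")
  }
  if (!(-1 < rho1 && rho1 < rho2 && rho2 <= 0))
    stop_param("rho1", "need -1 < rho1 < rho2 <= 0")
  if (!(0 <= rho3 && rho3 < rho4 && rho4 < 1))
    stop_param("rho3", "need 0 <= rho3 < rho4 < 1")
  structure(list(rho1 = rho1, rho2 = rho2, rho3 = rho3, rho4 = rho4),
            class = "silence_intervals")
}

#' @export
print.silence_intervals <- function(x, ...) {
  cat(sprintf("<silence_intervals> variation side [%g, %g], spreader side [%g, %g]\n",
              x$rho1, x$rho2, x$rho3, x$rho4))
  invisible(x)
}

# Internal vectorized classifier returning integer codes (2 = S, 3 = V, 4 = O).
classify_code <- function(x, rho) {
  out <- integer(length(x))
  s <- (x >= 0 & x < rho$rho3) | (x > rho$rho4 & x <= 1)
  v <- (x >= -1 & x < rho$rho1) | (x > rho$rho2 & x < 0)
  out[s] <- .CODE_S
  out[v] <- .CODE_V
  out[!s & !v] <- .CODE_O
  out
}

#' Classify an opinion value into a carrier role
#'
#' Total deterministic map from `[-1, 1]` to the carrier roles: spreader on
#' `[0, rho3) U (rho4, 1]`, variation on `[-1, rho1) U (rho2, 0)`, oyster on
#' the closed silence intervals `[rho1, rho2] U [rho3, rho4]`. Silence-interval
#' endpoints classify as oyster and `x = 0` as spreader, so every opinion
#' value maps to exactly one role.
#'
#' @param x numeric vector of opinion values in `[-1, 1]`.
#' @param rho a [silence_intervals()].
#' @return character vector of roles (`"S"`, `"V"`, `"O"`).
#' @examples
#' classify_opinion(c(-0.5, 0.25, 0.5, -0.1))
#' @export
classify_opinion <- function(x, rho = silence_intervals()) {
  if (!is.numeric(x)) stop_param("x", "opinion values must be numeric")
  if (any(is.na(x)) || any(x < -1 | x > 1))
    stop_param("x", "opinion values must lie in [-1, 1]")
  .state_label(classify_code(x, rho))
}

#' Mean opinion of a node's interacting neighbours
#'
#' The neighbour mean that drives the bounded-confidence update: the
#' arithmetic mean of opinions over neighbours that are carriers and
#' participating this step (offline-masked and recovered neighbours are
#' excluded; recovered opinions are frozen and never re-enter the mean).
#' When no such neighbour exists there is no interlocutor and the update is
#' skipped, signalled by `NA`.
#'
#' @param opinions numeric vector of the neighbours' opinion values.
#' @param states character vector of the neighbours' states (same length).
#' @param active logical vector marking neighbours participating this step
#'   (default all).
#' @return the mean opinion, or `NA_real_` when no carrier neighbour
#'   participates.
#' @examples
#' neighbor_mean_opinion(c(0.2, 0.4, 0.9), c("S", "V", "R"))  # 0.3
#' @export
neighbor_mean_opinion <- function(opinions, states, active = NULL) {
  if (length(opinions) != length(states))
    stop_param("states", "opinions and states must have equal length")
  if (is.null(active)) active <- rep(TRUE, length(states))
  keep <- is_carrier(states) & active & !is.na(opinions)
  if (!any(keep)) return(NA_real_)
  mean(opinions[keep])
}

#' Bounded-confidence opinion update
#'
#' Let `delta = |x - xbar|` with `xbar` the neighbour mean. Within the
#' assimilation distance (`delta < d1`) opinions attract:
#' `x' = x + mu (xbar - x)`; beyond the exclusion distance (`delta > d2`)
#' they repel and the difference widens: `x' = x + mu (x - xbar)`; in between
#' there is no willingness to interact and the opinion is unchanged. The
#' result is clamped to `[-1, 1]`. A ratchet protects committed spreaders:
#' once an opinion lies in `[0, rho3]` it cannot decrease
#' (`x' = max(x', x)`), so such a node can never drift back toward the
#' variation side.
#'
#' `literal = TRUE` restores the unsigned textbook forms
#' `x + mu * delta` / `x - mu * delta`, which coincide with the signed rules
#' when `x < xbar` but invert the geometry otherwise; it exists for
#' comparison, not for production use (see the methods vignette).
#'
#' @param x current opinion(s) in `[-1, 1]`.
#' @param xbar neighbour mean opinion(s); `NA` means no interlocutor (no
#'   update).
#' @param mu trust/convergence rate in `(0, 1]`.
#' @param d1 assimilation distance, `0 < d1 < d2`.
#' @param d2 exclusion distance.
#' @param rho a [silence_intervals()] (for the ratchet bound `rho3`).
#' @param literal use the unsigned printed update forms (default `FALSE`).
#' @return updated opinion(s), clamped to `[-1, 1]`.
#' @examples
#' opinion_update(0.1, 0.5)              # attraction: 0.14
#' opinion_update(0.9, -0.8)             # repulsion, clamped to 1
#' @export
opinion_update <- function(x, xbar, mu = 0.1, d1 = 1, d2 = 1.5,
                           rho = silence_intervals(), literal = FALSE) {
  if (!(mu > 0 && mu <= 1)) stop_param("mu", "need 0 < mu <= 1")
  if (!(d1 > 0 && d1 < d2)) stop_param("d1", "need 0 < d1 < d2")
  n <- max(length(x), length(xbar))
  x <- rep_len(x, n); xbar <- rep_len(xbar, n)
  out <- x
  has <- !is.na(xbar)
  delta <- abs(x - xbar)
  attract <- has & delta < d1
  repel <- has & delta > d2
  if (literal) {
    out[attract] <- x[attract] + mu * delta[attract]
    out[repel] <- x[repel] - mu * delta[repel]
  } else {
    out[attract] <- x[attract] + mu * (xbar[attract] - x[attract])
    out[repel] <- x[repel] + mu * (x[repel] - xbar[repel])
  }
  out <- clamp(out, -1, 1)
  ratchet <- x >= 0 & x <= rho$rho3
  out[ratchet] <- pmax(out[ratchet], x[ratchet])
  out
}

#' Draw an initial opinion consistent with a carrier role
#'
#' A node that has just entered the propagation state receives an opinion
#' drawn uniformly from the union of opinion-space intervals belonging to its
#' assigned role, each sub-interval weighted by its length (i.e. uniform on
#' the union). Supplying `u` makes the draw a deterministic inverse-CDF
#' transform, which the engine uses to keep all randomness on a replayable
#' tape.
#'
#' @param role carrier role, `"S"`, `"V"` or `"O"`.
#' @param rho a [silence_intervals()].
#' @param n number of draws (ignored when `u` is given).
#' @param u optional uniform variates in `[0, 1)` to transform.
#' @return numeric vector of opinions; `classify_opinion()` of the result
#'   always returns `role`.
#' @examples
#' range(initialize_opinion("O", n = 5))
#' @export
initialize_opinion <- function(role, rho = silence_intervals(), n = 1, u = NULL) {
  if (length(role) != 1L || !is_carrier(role))
    stop_param("role", "role must be one of S, V, O")
  if (is.null(u)) u <- stats::runif(n)
  eps <- 1e-9
  pieces <- switch(role,
    # [lo, hi) pairs; open ends nudged inward after the inverse-CDF map
    S = rbind(c(0, rho$rho3, 0), c(rho$rho4, 1, 1)),        # third col: 1 = open lower end
    V = rbind(c(-1, rho$rho1, 0), c(rho$rho2, 0, 1)),
    O = rbind(c(rho$rho1, rho$rho2, 0), c(rho$rho3, rho$rho4, 0)))
  len <- pieces[, 2] - pieces[, 1]
  tot <- sum(len)
  s <- u * tot
  first <- s < len[1]
  out <- ifelse(first, pieces[1, 1] + s, pieces[2, 1] + (s - len[1]))
  # keep draws off boundary points that would classify into a different role
  open_lower <- !first & pieces[2, 3] == 1
  out[open_lower] <- pmax(out[open_lower], pieces[2, 1] + eps)
  if (role != "O") {
    # upper ends of [0, rho3) and [-1, rho1) are open
    hit <- first & out >= pieces[1, 2]
    out[hit] <- pieces[1, 2] - eps
  }
  out
}
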