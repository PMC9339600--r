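#' Node states of the ISOVR model
#'
#' The state space is Ignorant (`"I"`), Spreader (`"S"`), Variation (`"V"`),
#' Oyster (`"O"`) and Recovered (`"R"`). Spreaders, variations and oysters
#' jointly constitute the rumor *carriers*: nodes that hold the rumor (and an
#' opinion value) and exert influence on their neighbourhood. Recovered is
#' absorbing: a recovered node never re-enters any other state.
#'
#' @return `node_states()` returns the five state labels in canonical order;
#'   `carrier_states()` the three carrier labels.
#' @examples
#' node_states()
#' is_carrier(c("I", "S", "V", "O", "R"))
#' @export
node_states <- function() c("I", "S", "V", "O", "R")

#' @rdname node_states
#' @export
carrier_states <- function() c("S", "V", "O")

#' @rdname node_states
#' @param state character vector of state labels.
#' @export
is_carrier <- function(state) state %in% carrier_states()

# Integer codes used internally by the engine (1..5 in canonical order).
.state_code <- function(state) {
  code <- match(state, node_states())
  if (anyNA(code)) stop_param("state", "unknown node state label")
  code
}
.state_label <- function(code) node_states()[code]
.CODE_I <- 1L; .CODE_S <- 2L; .CODE_V <- 3L; .CODE_O <- 4L; .CODE_R <- 5L
.is_carrier_code <- function(code) code >= 2L & code <= 4L
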