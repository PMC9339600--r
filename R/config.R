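# SimConfig: the complete parameter vector of the model, with validation.

# Field definitions: default value and validation predicate (message).
.config_fields <- function() {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
  list(
    schema_version = list(1L, function(x) num1(x) && x == 1, "must be 1"),
    n = list(2000L, function(x) num1(x) && x >= 2 && x == floor(x), "must be an integer >= 2"),
    m = list(5L, function(x) num1(x) && x >= 1 && x == floor(x), "must be an integer >= 1"),
    seed = list(1L, function(x) num1(x) && x == floor(x), "must be an integer"),
    horizon = list(100L, function(x) num1(x) && x >= 0 && x == floor(x), "must be an integer >= 0"),
    initial_carriers = list(NA_integer_, function(x)
      (length(x) == 1L && is.na(x)) || (is.numeric(x) && length(x) == 1L && x >= 0 && x == floor(x)),
      "must be NA (1% of n) or an integer >= 0"),
    initial_opinion = list("uniform", function(x) x %in% c("uniform", "role_interval"),
      "must be 'uniform' or 'role_interval'"),
    phi_mean = list(0.2, num1, "must be a number"),
    phi_sd = list(0.5, function(x) num1(x) && x >= 0, "must be >= 0"),
    varphi_mean = list(0.2, num1, "must be a number"),
    varphi_sd = list(0.15, function(x) num1(x) && x >= 0, "must be >= 0"),
    immune_start = list(15L, function(x) num1(x) && x >= 0 && x == floor(x), "must be an integer >= 0"),
    extinction_direction = list("prose", function(x) x %in% c("prose", "as_printed"),
      "must be 'prose' or 'as_printed'"),
    ignorant_direct_immunity = list(FALSE, flag, "must be TRUE/FALSE"),
    offline_prob = list(0.97, function(x) num1(x) && x >= 0 && x <= 1, "must lie in [0, 1]"),
    invert_offline = list(FALSE, flag, "must be TRUE/FALSE"),
    xi = list(0.1, function(x) num1(x) && x >= 0, "must be >= 0"),
    reinforcement = list(0.2, function(x) num1(x) && x > 0 && x < 1, "must lie in (0, 1)"),
    sync_direction = list("online_to_offline", function(x)
      x %in% c("online_to_offline", "bidirectional"),
      "must be 'online_to_offline' or 'bidirectional'"),
    alpha_s = list(1, function(x) num1(x) && x > 0, "must be > 0"),
    alpha_v = list(1.5, function(x) num1(x) && x > 0, "must be > 0"),
    alpha_o = list(0.5, function(x) num1(x) && x > 0, "must be > 0"),
    mu = list(0.1, function(x) num1(x) && x > 0 && x <= 1, "must lie in (0, 1]"),
    d1 = list(1, function(x) num1(x) && x > 0, "must be > 0"),
    d2 = list(1.5, function(x) num1(x) && x > 0, "must be > 0"),
    rho1 = list(-0.4, num1, "must be a number"),
    rho2 = list(-0.2, num1, "must be a number"),
    rho3 = list(0.2, num1, "must be a number"),
    rho4 = list(0.3, num1, "must be a number"),
    literal_opinion_rule = list(FALSE, flag, "must be TRUE/FALSE"),
    coupling_mode = list("random", function(x)
      x %in% c("random", "assortative", "disassortative"),
      "must be 'random', 'assortative' or 'disassortative'"),
    offline_topology = list("ba", function(x) x %in% c("ba", "ws"),
      "must be 'ba' (scale-free) or 'ws' (small-world)"),
    record_statelog = list(FALSE, flag, "must be TRUE/FALSE")
  )
}

#' Simulation configuration
#'
#' Assembles and validates the full parameter vector of the coupled-network
#' rumor model. All defaults are the case-study parameterization: a
#' scale-free layer with `n = 2000`, `m = 5` (mean degree ~10), offline
#' probability `0.97`, arousal threshold distribution `N(0.2, 0.5)` and
#' extinguishing threshold distribution `N(0.2, 0.15)` (both truncated to
#' `[0, 1]`), synchronization `xi = 0.1` with reinforcement `gamma = 0.2`,
#' attribute influences `alpha_s = 1`, `alpha_v = 1.5`, `alpha_o = 0.5`,
#' immunity onset at step 15, trust rate `mu = 0.1` with assimilation
#' distance `d1 = 1` and exclusion distance `d2 = 1.5`, and silence
#' coefficients `rho1 = -0.4`, `rho2 = -0.2`, `rho3 = 0.2`, `rho4 = 0.3`.
#'
#' @param ... named parameter overrides; unknown names raise an error, and
#'   every value is range-checked with an error naming the offending field.
#'   See the methods vignette for the meaning and units of each parameter.
#' @return an object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n = 500, horizon = 30)
#' cfg$xi
#' @export
sim_config <- function(...) {
  fields <- .config_fields()
  args <- list(...)
  if (length(args) && (is.null(names(args)) || any(names(args) == "")))
    stop_param("...", "all configuration arguments must be named")
  unknown <- setdiff(names(args), names(fields))
  if (length(unknown))
    stop_param(unknown[1], "unknown configuration key")
  cfg <- lapply(fields, `[[`, 1)
  for (nm in names(args)) {
    val <- args[[nm]]
    def <- fields[[nm]][[1]]
    # normalize numeric storage so configs compare equal across file formats
    if (length(val) == 1L && is.na(val) && is.integer(def)) val <- NA_integer_
    else if (is.numeric(val) && length(val) == 1L && !is.na(val)) {
      if (is.integer(def) && val == floor(val)) val <- as.integer(val)
      else if (is.double(def)) val <- as.double(val)
    }
    cfg[[nm]] <- val
  }
  class(cfg) <- "sim_config"
  validate_config(cfg)
}

#' @rdname sim_config
#' @param config a `sim_config` object (or plain named list) to validate.
#' @export
validate_config <- function(config) {
  fields <- .config_fields()
  for (nm in names(fields)) {
    if (is.null(config[[nm]])) stop_param(nm, "missing configuration key")
    if (!fields[[nm]][[2]](config[[nm]])) stop_param(nm, fields[[nm]][[3]])
  }
  if (config$n <= config$m)
    stop_param("n", "node count n must exceed attachment parameter m")
  if (!(config$d1 < config$d2))
    stop_param("d2", "exclusion distance d2 must exceed assimilation distance d1")
  # silence interval ordering (-1 < rho1 < rho2 <= 0 <= rho3 < rho4 < 1)
  silence_intervals(config$rho1, config$rho2, config$rho3, config$rho4)
  if (!is.na(config$initial_carriers) && config$initial_carriers > config$n)
    stop_param("initial_carriers", "cannot exceed node count n")
  if (config$phi_sd == 0 && (config$phi_mean < 0 || config$phi_mean > 1))
    stop_param("phi_mean", "degenerate threshold must lie in [0, 1]")
  if (config$varphi_sd == 0 && (config$varphi_mean < 0 || config$varphi_mean > 1))
    stop_param("varphi_mean", "degenerate threshold must lie in [0, 1]")
  config
}

# Number of initially seeded carriers (1% of n unless given explicitly).
n_initial_carriers <- function(config) {
  if (is.na(config$initial_carriers)) max(1L, round(0.01 * config$n)) else
    as.integer(config$initial_carriers)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> n = %d, m = %d, horizon = %d, seed = %d\n",
              x$n, x$m, x$horizon, x$seed))
  cat(sprintf("  thresholds: arousal N(%g, %g), extinguish N(%g, %g), immunity from t = %d (%s)\n",
              x$phi_mean, x$phi_sd, x$varphi_mean, x$varphi_sd,
              x$immune_start, x$extinction_direction))
  cat(sprintf("  coupling: o = %g, xi = %g, gamma = %g, %s, %s links\n",
              x$offline_prob, x$xi, x$reinforcement, x$sync_direction, x$coupling_mode))
  cat(sprintf("  influence: alpha_S = %g, alpha_V = %g, alpha_O = %g\n",
              x$alpha_s, x$alpha_v, x$alpha_o))
  cat(sprintf("  opinions: mu = %g, d1 = %g, d2 = %g, rho = (%g, %g, %g, %g)\n",
              x$mu, x$d1, x$d2, x$rho1, x$rho2, x$rho3, x$rho4))
  invisible(x)
}
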