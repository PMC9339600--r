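# Configuration files, CSV/JSON outputs, graph files and fixture presets.

#' Read a simulation configuration file
#'
#' YAML (`.yaml`/`.yml`) or JSON (`.json`), auto-detected by extension. Keys
#' mirror the [sim_config()] arguments; missing keys are filled with the
#' default parameterization, unknown keys and out-of-range values raise an
#' error naming the offending key. An empty file yields the full default
#' configuration.
#'
#' @param path path to the configuration file.
#' @return a validated [sim_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_param("path", sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  # YAML 1.1 treats bare y/n/yes/no as booleans, which would turn the key
  # `n` into FALSE; only accept spelled-out true/false variants as logicals
  bool_handlers <- list(
    "bool#yes" = function(x) if (tolower(x) %in% c("true", "yes", "on")) TRUE else x,
    "bool#no"  = function(x) if (tolower(x) %in% c("false", "no", "off")) FALSE else x)
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path, handlers = bool_handlers),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop_param("path", "unsupported config extension (use .yaml, .yml or .json)"))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop_param("path", "config file must contain a key-value mapping")
  do.call(sim_config, raw)
}

#' @rdname read_config
#' @param config a [sim_config()] to serialize.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  ext <- tolower(tools::file_ext(path))
  obj <- unclass(config)
  obj$initial_carriers <- if (is.na(obj$initial_carriers)) NULL else obj$initial_carriers
  switch(ext,
    yaml = , yml = yaml::write_yaml(obj, path),
    json = jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop_param("path", "unsupported config extension (use .yaml, .yml or .json)"))
  invisible(path)
}

#' Write / read the density time series as CSV
#'
#' Column order `t,layer,I,S,V,O,R,C`, rows ordered by `(t, layer)`,
#' densities formatted to 6 decimals (round-trip accurate to 1e-6).
#'
#' @param ts a timeseries data.frame from [sim_timeseries()] (or a
#'   `sim_result`).
#' @param path output path.
#' @export
write_timeseries <- function(ts, path) {
  if (inherits(ts, "sim_result")) ts <- ts$timeseries
  if (!is.data.frame(ts) || nrow(ts) == 0) stop_param("ts", "need a non-empty time series")
  out <- ts[order(ts$t, match(ts$layer, .LAYERS)), , drop = FALSE]
  for (col in c("I", "S", "V", "O", "R", "C"))
    out[[col]] <- sprintf("%.6f", out[[col]])
  utils::write.csv(out[c("t", "layer", "I", "S", "V", "O", "R", "C")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop_param("path", sprintf("file not found: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a run summary as JSON
#'
#' @param result a `sim_result` from [run_sim()].
#' @param path output path.
#' @export
write_summary <- function(result, path) {
  sm <- if (is.data.frame(result)) result else result$summary
  obj <- lapply(split(sm, sm$layer), function(d)
    list(peak_c = d$peak_c, peak_c_time = d$peak_c_time,
         peak_o = d$peak_o, final_r = d$final_r))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write layer graphs
#'
#' Whitespace-delimited edge lists (node ids are 0-based integers) and
#' GraphML, auto-detected by extension (`.edgelist`/`.txt` vs `.graphml`).
#' `n` pads an edge list with isolated nodes when the highest id is below
#' `n - 1`.
#'
#' @param path graph file path.
#' @param n optional node count for edge-list input.
#' @return an undirected `igraph` graph.
#' @export
read_layer_graph <- function(path, n = NULL) {
  if (!file.exists(path)) stop_param("path", sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(igraph::as_undirected(g, mode = "collapse"))
  }
  el <- utils::read.table(path, header = FALSE,
                          colClasses = "integer")[, 1:2, drop = FALSE]
  nodes <- if (is.null(n)) max(el) + 1L else as.integer(n)
  igraph::graph_from_edgelist(as.matrix(el) + 1L, directed = FALSE) |>
    igraph::add_vertices(max(0L, nodes - max(el) - 1L))
}

#' @rdname read_layer_graph
#' @param g an `igraph` graph to write.
#' @export
write_layer_graph <- function(g, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g, names = FALSE) - 1L
    utils::write.table(el, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# Frozen 12-node two-layer toy topology (0-based pairs, stable across
# versions; used by tests and the step-replay oracle).
.toy12_edges <- function() {
  list(
    online = matrix(c(
      0,1, 0,2, 1,2, 2,3, 3,4, 4,5, 5,6, 6,7, 7,8, 8,9, 9,10, 10,11,
      11,0, 1,6, 4,9), ncol = 2, byrow = TRUE),
    offline = matrix(c(
      0,1, 1,2, 2,3, 3,4, 4,5, 5,0, 6,7, 7,8, 8,9, 9,10, 10,11, 11,6,
      0,6, 3,9, 1,7, 4,10), ncol = 2, byrow = TRUE))
}

#' Deterministic fixture networks and configurations
#'
#' Presets for tests and demos: `"toy12"` (two hand-specified 12-node layer
#' graphs with random coupling and a small fast configuration), `"star"`
#' (two 8-node stars), `"complete"` (two copies of K6) and
#' `"case_study"` (two scale-free layers at the full case-study size with
#' the default parameterization).
#'
#' @param preset one of `"toy12"`, `"star"`, `"complete"`, `"case_study"`.
#' @param seed integer seed (default 1).
#' @return a list with elements `network` (a [couple_layers()] result) and
#'   `config` (a [sim_config()]).
#' @examples
#' fx <- make_fixture("toy12")
#' igraph::vcount(fx$network$online)
#' @export
make_fixture <- function(preset = c("toy12", "star", "complete", "case_study"),
                         seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "toy12") {
    e <- .toy12_edges()
    g1 <- igraph::graph_from_edgelist(e$online + 1L, directed = FALSE)
    g2 <- igraph::graph_from_edgelist(e$offline + 1L, directed = FALSE)
    cfg <- sim_config(n = 12, m = 2, seed = seed, horizon = 20,
                      initial_carriers = 2, offline_prob = 0.5,
                      immune_start = 5, record_statelog = TRUE)
    net <- couple_layers(g1, g2, mode = "random", seed = seed)
  } else if (preset == "star") {
    g <- igraph::make_star(8, mode = "undirected")
    cfg <- sim_config(n = 8, m = 1, seed = seed, horizon = 10,
                      initial_carriers = 1, offline_prob = 0.5)
    net <- couple_layers(g, g, mode = "random", seed = seed)
  } else if (preset == "complete") {
    g <- igraph::make_full_graph(6)
    cfg <- sim_config(n = 6, m = 1, seed = seed, horizon = 10,
                      initial_carriers = 1, offline_prob = 0.5)
    net <- couple_layers(g, g, mode = "random", seed = seed)
  } else {
    cfg <- sim_config(seed = seed)
    g1 <- with_seed(seed, build_ba_network(cfg$n, cfg$m))
    g2 <- with_seed(seed + 1L, build_ba_network(cfg$n, cfg$m))
    net <- couple_layers(g1, g2, mode = cfg$coupling_mode, seed = seed)
  }
  list(network = net, config = cfg)
}
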