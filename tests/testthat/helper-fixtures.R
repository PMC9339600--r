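# Small graphs and fast configurations shared across tests.

path_graph <- function(n) igraph::make_ring(n, circular = FALSE)

quick_config <- function(...) {
  defaults <- list(n = 60, m = 2, horizon = 10, seed = 42,
                   offline_prob = 0.5, initial_carriers = 3)
  sim_config_args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, sim_config_args)
}

# Density table for one layer from a sim_result
layer_ts <- function(res, layer) {
  ts <- res$timeseries
  ts[ts$layer == layer, , drop = FALSE]
}
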