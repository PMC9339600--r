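test_that("initialization seeds counterpart carriers and records t = 0", {
  cfg <- quick_config(initial_carriers = 0)
  st <- initialize_sim(cfg)
  d <- st$densities[[1]]
  expect_equal(d$online[["I"]], 1)
  expect_equal(d$offline[["I"]], 1)
  # no seed: the trajectory is constant forever
  res <- run_sim(cfg)
  expect_true(all(res$timeseries$I == 1))

  cfg <- sim_config(n = 2000, m = 5, horizon = 0, seed = 5)
  st <- initialize_sim(cfg)
  expect_equal(sum(is_carrier(.state_label_oracle(st$states$online))) / 2000, 0.01)
  d <- st$densities[[1]]
  expect_equal(d$online[["S"]] + d$online[["V"]] + d$online[["O"]], 0.01)

  a <- initialize_sim(quick_config())
  b <- initialize_sim(quick_config())
  expect_identical(a$states, b$states)
  expect_identical(a$opinions, b$opinions)
  expect_identical(a$phi, b$phi)
})

test_that("a state with zero carriers is a fixed point of the step map", {
  cfg <- quick_config(initial_carriers = 0, horizon = 3)
  st <- initialize_sim(cfg)
  st2 <- sim_step(st)
  expect_identical(st2$states, st$states)
  expect_identical(st2$opinions, st$opinions)
})

test_that("densities are conserved and the carrier identity is structural", {
  res <- run_sim(quick_config(horizon = 25, record_statelog = TRUE))
  ts <- res$timeseries
  expect_lt(max(abs(ts$I + ts$S + ts$V + ts$O + ts$R - 1)), 1e-12)
  expect_identical(ts$C, ts$S + ts$V + ts$O)
  expect_equal(nrow(ts), 26 * 2)
})

test_that("recovery is absorbing and appears only after immunity onset", {
  res <- run_sim(quick_config(n = 80, horizon = 25, seed = 17,
                              record_statelog = TRUE))
  ts <- res$timeseries
  expect_true(all(ts$R[ts$t < 15] == 0))
  for (l in c("online", "offline"))
    expect_true(all(diff(layer_ts(res, l)$R) >= 0))
  # per-node scan of the full state log: R never transitions away
  log <- res$statelog
  for (l in c("online", "offline")) {
    d <- log[log$layer == l, ]
    m <- matrix(d$state, nrow = length(unique(d$node)))  # node x time
    for (i in seq_len(nrow(m))) {
      r <- which(m[i, ] == "R")
      if (length(r)) expect_true(all(m[i, r[1]:ncol(m)] == "R"))
    }
  }
})

test_that("opinions stay in [-1, 1] and the spreader ratchet holds on trajectories", {
  # xi = 0: a synchronization event may replace an offline carrier's opinion
  # with its counterpart's, which is outside the ratchet's scope
  res <- run_sim(quick_config(n = 80, horizon = 25, seed = 23, xi = 0,
                              record_statelog = TRUE))
  log <- res$statelog
  op <- log$opinion[!is.na(log$opinion)]
  expect_true(all(op >= -1 & op <= 1))
  rho3 <- res$config$rho3
  for (l in c("online", "offline")) {
    d <- log[log$layer == l, ]
    nodes <- unique(d$node)
    s <- matrix(d$state, nrow = length(nodes))
    x <- matrix(d$opinion, nrow = length(nodes))
    for (i in seq_along(nodes)) {
      carrier_run <- s[i, ] %in% c("S", "V", "O")
      for (tt in seq_len(ncol(s) - 1)) {
        if (carrier_run[tt] && carrier_run[tt + 1] &&
            !is.na(x[i, tt]) && x[i, tt] >= 0 && x[i, tt] <= rho3)
          expect_gte(x[i, tt + 1], x[i, tt])
      }
    }
  }
})

test_that("runs are reproducible and horizon zero yields initial densities only", {
  cfg <- quick_config(horizon = 8)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_timeseries(run_sim(cfg), f1)
  write_timeseries(run_sim(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  res0 <- run_sim(quick_config(horizon = 0))
  expect_equal(unique(res0$timeseries$t), 0)
  expect_equal(nrow(res0$timeseries), 2)
})

test_that("run summaries report peaks and final recovered density", {
  res <- run_sim(quick_config(n = 80, horizon = 25, seed = 3))
  sm <- res$summary
  expect_setequal(sm$layer, c("online", "offline"))
  for (i in 1:2) {
    d <- layer_ts(res, sm$layer[i])
    expect_equal(sm$peak_c[i], max(d$C))
    expect_equal(d$C[d$t == sm$peak_c_time[i]], sm$peak_c[i])
    expect_equal(sm$peak_o[i], max(d$O))
    expect_equal(sm$final_r[i], d$R[nrow(d)])
    expect_true(all(unlist(sm[i, -1]) >= 0))
  }
})

test_that("sweeps run replicated seeded simulations in tidy form", {
  cfg <- quick_config(n = 40, horizon = 6)
  sw <- sweep_sim(cfg, "alpha_v", c(1.5, 2.5), replicates = 3)
  expect_equal(nrow(sw), 2 * 3 * 2)  # values x replicates x layers
  expect_setequal(unique(sw$value), c(1.5, 2.5))
  agg <- summarize_sweep(sw)
  expect_equal(nrow(agg), 4)
  expect_true(all(c("peak_c_mean", "peak_c_sd") %in% names(agg)))

  # degenerate sweep equals a direct run with the same derived seed
  sw1 <- sweep_sim(cfg, "xi", 0.1, replicates = 1)
  direct <- run_sim(do.call(sim_config,
    utils::modifyList(unclass(cfg), list(xi = 0.1, seed = sw1$seed[1]))))
  expect_equal(sw1$peak_c, direct$summary$peak_c)

  # full reproducibility of every cell
  sw2 <- sweep_sim(cfg, "alpha_v", c(1.5, 2.5), replicates = 3)
  expect_identical(sw, sw2)

  expect_error(sweep_sim(cfg, "nope", 1), "param")
})

test_that("the step map matches the per-node brute-force oracle on toy12", {
  fx <- make_fixture("toy12", seed = 6)
  st <- initialize_sim(fx$config, online = fx$network$online,
                       offline = fx$network$offline)
  set.seed(99)
  for (k in 1:8) {
    tape <- draw_tape(st)
    want <- oracle_step(st, tape)
    st <- sim_step(st, tape)
    got_states <- lapply(st$states, .state_label_oracle)
    expect_identical(got_states, want$states)
    expect_equal(st$opinions, want$opinions, tolerance = 1e-12)
  }
})

test_that("the oracle also agrees under bidirectional sync and printed extinction", {
  fx <- make_fixture("toy12", seed = 8)
  cfg <- do.call(sim_config, utils::modifyList(unclass(fx$config),
    list(sync_direction = "bidirectional", extinction_direction = "as_printed",
         xi = 0.4)))
  st <- initialize_sim(cfg, online = fx$network$online,
                       offline = fx$network$offline)
  set.seed(101)
  for (k in 1:8) {
    tape <- draw_tape(st)
    want <- oracle_step(st, tape)
    st <- sim_step(st, tape)
    expect_identical(lapply(st$states, .state_label_oracle), want$states)
    expect_equal(st$opinions, want$opinions, tolerance = 1e-12)
  }
})
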