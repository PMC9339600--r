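test_that("BA generator produces connected scale-free layers at the right scale", {
  g <- build_ba_network(2000, 5, seed = 11)
  expect_true(igraph::is_connected(g))
  k <- 2 * igraph::ecount(g) / igraph::vcount(g)
  expect_lt(abs(k - 10) / 10, 0.01)

  tiny <- build_ba_network(2, 1, seed = 1)
  expect_equal(igraph::ecount(tiny), 1)
  expect_equal(mean(igraph::degree(tiny)), 1.0)

  d1 <- igraph::degree(build_ba_network(50, 3, seed = 5))
  d2 <- igraph::degree(build_ba_network(50, 3, seed = 5))
  expect_identical(d1, d2)

  expect_error(build_ba_network(3, 5), "must exceed")
})

test_that("BA mean degree is stable near 2m across seeds", {
  ks <- vapply(1:20, function(s) {
    g <- build_ba_network(2000, 5, seed = s)
    2 * igraph::ecount(g) / igraph::vcount(g)
  }, numeric(1))
  expect_true(all(ks >= 9.9 & ks <= 10.0))
})

test_that("coupling modes map degree ranks as specified", {
  s <- igraph::make_star(5, mode = "undirected")  # hub is node 1
  net_a <- couple_layers(s, s, mode = "assortative")
  expect_equal(net_a$mapping[1], 1)               # hub -> hub
  net_d <- couple_layers(s, s, mode = "disassortative")
  expect_true(net_d$mapping[1] != 1)              # hub -> a leaf
  # leaves tie on degree; ascending-id tie-break makes this deterministic
  expect_equal(net_d$mapping[1], 2)

  r1 <- couple_layers(s, s, mode = "random", seed = 9)$mapping
  r2 <- couple_layers(s, s, mode = "random", seed = 9)$mapping
  expect_identical(r1, r2)
  expect_setequal(r1, 1:5)

  expect_error(couple_layers(s, igraph::make_star(6, mode = "undirected")),
               "sizes differ")
})

test_that("degree centrality is the neighbour fraction", {
  expect_equal(degree_centrality(igraph::make_full_graph(5)), rep(1, 5))
  s <- igraph::make_star(5, mode = "undirected")
  expect_equal(degree_centrality(s, 1), 1.0)
  expect_equal(degree_centrality(s, 2), 0.25)
  expect_equal(unname(degree_centrality(path_graph(3), 2)), 1.0)
  expect_error(degree_centrality(igraph::make_empty_graph(1, directed = FALSE)),
               "at least 2 nodes")
})

test_that("degree centrality matches a brute-force adjacency count", {
  for (s in 1:5) {
    g <- igraph::sample_gnp(sample(5:20, 1), 0.3, directed = FALSE)
    if (igraph::vcount(g) < 2) next
    a <- as.matrix(igraph::as_adjacency_matrix(g))
    expect_equal(unname(degree_centrality(g)),
                 rowSums(a) / (igraph::vcount(g) - 1))
  }
})

test_that("eigenvector centrality satisfies the dominant fixed point", {
  # vertex-transitive graph: all centralities equal
  ec <- eigen_centrality_power(igraph::make_full_graph(4))
  expect_equal(ec, rep(0.5, 4), tolerance = 1e-9)

  # star: hub / leaf ratio is sqrt(n - 1) in closed form
  ec <- eigen_centrality_power(igraph::make_star(10, mode = "undirected"))
  expect_equal(ec[1] / ec[2], sqrt(9), tolerance = 1e-8)

  # random graph: match the dense eigendecomposition oracle and the
  # fixed-point relation A x = lambda x
  set.seed(7)
  g <- igraph::sample_gnp(10, 0.4, directed = FALSE)
  ec <- eigen_centrality_power(g)
  expect_equal(ec, dense_eigen_centrality(g), tolerance = 1e-8)
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  lambda <- drop(ec %*% a %*% ec)
  expect_lt(max(abs(a %*% ec - lambda * ec)), 1e-8)
  expect_equal(sum(ec^2), 1, tolerance = 1e-12)

  expect_warning(ec0 <- eigen_centrality_power(igraph::make_empty_graph(3, directed = FALSE)),
                 "no edges")
  expect_equal(ec0, rep(0, 3))
})

test_that("attribute influence returns the per-role weights", {
  cfg <- sim_config()
  expect_equal(attribute_influence("S", cfg), 1.0)
  expect_equal(attribute_influence("V", cfg), 1.5)
  expect_equal(attribute_influence("O", cfg), 0.5)
  expect_equal(attribute_influence(c("O", "S"), cfg), c(0.5, 1.0))
  expect_error(attribute_influence("I", cfg), "carrier states")
  expect_error(attribute_influence("R", cfg), "carrier states")
})

test_that("combined influence is the product of its three factors", {
  g <- igraph::make_full_graph(4)
  br <- node_influence(g, 1:4, "S")
  expect_equal(br$influence, br$DE * br$EC * br$Ar)
  # symmetry: equal factors on a vertex-transitive graph
  expect_equal(length(unique(round(br$influence, 12))), 1L)

  # variation role scales influence by alpha_v
  brv <- node_influence(g, 1, "V")
  expect_equal(brv$influence, br$influence[1] * 1.5)

  # isolated node has zero eigenvector centrality, hence zero influence
  g2 <- igraph::add_vertices(igraph::make_full_graph(4), 1)
  expect_equal(node_influence(g2, 5, "S")$influence, 0)
})

test_that("influence is invariant under node relabeling", {
  set.seed(3)
  for (rep in 1:3) {
    g <- igraph::sample_gnp(8, 0.4, directed = FALSE)
    perm <- sample(8)
    gp <- igraph::permute(g, perm)
    inf <- node_influence(g, 1:8, "S")$influence
    infp <- node_influence(gp, 1:8, "S")$influence
    expect_equal(infp[perm], inf, tolerance = 1e-9)
  }
})
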