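test_that("opinion classification maps the silence intervals to roles", {
  rho <- silence_intervals(-0.4, -0.2, 0.2, 0.3)
  expect_equal(classify_opinion(-0.5, rho), "V")
  expect_equal(classify_opinion(0.25, rho), "O")
  expect_equal(classify_opinion(0.5, rho), "S")
  expect_equal(classify_opinion(-0.1, rho), "V")
  # boundary points: silence endpoints are O, zero is S
  expect_equal(classify_opinion(c(-0.4, -0.2, 0.2, 0.3), rho), rep("O", 4))
  expect_equal(classify_opinion(0, rho), "S")
  expect_equal(classify_opinion(c(-1, 1), rho), c("V", "S"))
  expect_error(classify_opinion(1.1, rho), "\\[-1, 1\\]")
})

test_that("classification is total on a fine opinion grid", {
  grid <- seq(-1, 1, length.out = 1e4)
  roles <- classify_opinion(grid)
  expect_true(all(roles %in% c("S", "V", "O")))
  expect_equal(length(roles), 1e4)
})

test_that("silence interval ordering is validated", {
  expect_error(silence_intervals(rho1 = -0.1, rho2 = -0.2), "rho1")
  expect_error(silence_intervals(rho3 = 0.4, rho4 = 0.3), "rho3")
})

test_that("neighbour mean uses participating carriers only", {
  expect_equal(neighbor_mean_opinion(c(0.2, 0.4), c("S", "V")), 0.3)
  expect_true(is.na(neighbor_mean_opinion(c(0.2, 0.4), c("I", "R"))))
  expect_equal(neighbor_mean_opinion(c(0.6, NA, 0.9), c("S", "I", "R")), 0.6)
  # masked carriers are excluded
  expect_equal(neighbor_mean_opinion(c(0.2, 0.8), c("S", "S"),
                                     active = c(TRUE, FALSE)), 0.2)
})

test_that("bounded-confidence update attracts, repels and clamps", {
  expect_equal(opinion_update(0.1, 0.5), 0.14)
  expect_equal(opinion_update(0.5, 0.5), 0.5)                 # fixed point
  expect_equal(opinion_update(0.9, -0.8), 1.0)                # repulsion, clamped
  expect_equal(opinion_update(0.15, -0.9), 0.15)              # neutral zone
  expect_equal(opinion_update(0.4, NA), 0.4)                  # no interlocutor
})

test_that("attraction contracts and repulsion expands by the trust rate", {
  set.seed(8)
  mu <- 0.1
  for (i in 1:100) {
    x <- runif(1, -0.3, 0.3); xb <- x + runif(1, -0.9, 0.9)
    if (x >= 0 && x <= 0.2 && xb < x) next  # ratchet binds; covered below
    out <- opinion_update(x, xb, mu = mu)
    expect_equal(abs(out - xb), (1 - mu) * abs(x - xb), tolerance = 1e-12)
  }
  for (i in 1:100) {
    x <- runif(1, 0.55, 0.8); xb <- x - runif(1, 1.51, 1.7)
    out <- opinion_update(x, xb, mu = mu)
    if (x + mu * (x - xb) > 1) next         # clamp binds
    expect_equal(abs(out - xb), (1 + mu) * abs(x - xb), tolerance = 1e-12)
  }
})

test_that("the spreader ratchet prevents any decrease on [0, rho3]", {
  # attraction toward a lower mean would decrease x; the ratchet holds it
  expect_equal(opinion_update(0.15, -0.5), 0.15)
  expect_equal(opinion_update(0.15, 0.05), 0.15)
  # above rho3 the same pull does act
  expect_lt(opinion_update(0.5, 0.05), 0.5)
})

test_that("literal update forms reproduce the printed absolute-value rule", {
  # x < xbar: literal and signed coincide
  expect_equal(opinion_update(0.1, 0.5, literal = TRUE), 0.14)
  # x > xbar: literal attraction moves x away from xbar (the printed form)
  expect_equal(opinion_update(0.5, 0.3, literal = TRUE), 0.52)
  expect_equal(opinion_update(0.5, 0.3, literal = FALSE), 0.48)
})

test_that("initial opinions are consistent with the assigned role", {
  rho <- silence_intervals()
  x <- initialize_opinion("O", rho, n = 200)
  expect_true(all((x >= -0.4 & x <= -0.2) | (x >= 0.2 & x <= 0.3)))
  for (role in c("S", "V", "O")) {
    x <- initialize_opinion(role, rho, n = 500)
    expect_true(all(classify_opinion(x, rho) == role))
  }
  expect_error(initialize_opinion("I"), "role")
})

test_that("initial opinion mass is proportional to sub-interval length", {
  # variation intervals [-1, -0.4) and (-0.2, 0) have lengths 0.6 and 0.2
  set.seed(13)
  x <- initialize_opinion("V", n = 1e5)
  p <- 0.6 / 0.8
  phat <- mean(x < -0.4)
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(phat - p), 3 * se)
})
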