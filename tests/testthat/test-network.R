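test_that("encoding normalization is exact on level blocks", {
  sp <- small_pipeline()
  H <- normalize_encodings(sp$ml)
  expect_true(all(abs(colSums(H) - 1) < 1e-12))
  # block structure: each column equals the concatenated column / #levels
  L <- length(sp$ml$levels)
  expect_equal(H, sp$ml$H_star / L, tolerance = 1e-8)

  # single level: identity
  one <- sp$ml$levels[[1]]$H
  expect_equal(normalize_encodings(one), one, tolerance = 1e-12)

  bad <- cbind(c(1, 0), c(0, 0))
  expect_error(normalize_encodings(bad), "zero")
  expect_error(normalize_encodings(-one), "non-negative")
})

test_that("the Jensen-Shannon metric matches direct evaluation", {
  expect_equal(jsd_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jsd_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(jsd_distance(c(0.5, 0.5), c(1, 0)), 0.55790, tolerance = 1e-4)
  expect_equal(jsd_distance(c(0.5, 0.5), c(1, 0)),
               jsd_oracle(c(0.5, 0.5), c(1, 0)), tolerance = 1e-12)
  expect_error(jsd_distance(c(1, 0), c(0.5, 0.25, 0.25)), "length")
  expect_error(jsd_distance(c(1.2, -0.2), c(0.5, 0.5)), "negative")
})

test_that("the metric axioms hold on random triples", {
  set.seed(101)
  for (i in seq_len(10000)) {
    len <- sample(2:6, 1)
    a <- rprob(len); b <- rprob(len); cc <- rprob(len)
    dab <- jsd_distance(a, b)
    expect_identical(dab, jsd_distance(b, a))
    if (dab < 0 || dab > 1) fail("distance out of [0,1]")
    if (jsd_distance(a, cc) > dab + jsd_distance(b, cc) + 1e-12)
      fail("triangle inequality violated")
  }
  succeed()
})

test_that("neighbor-count selection follows the printed procedure", {
  # one near neighbor, far plateau: breaks almost immediately
  beta <- c(0.1, 5, 5.1, 5.2, 5.3, 5.4)
  expect_equal(kstar_neighbors(beta), kstar_oracle(beta))
  expect_lte(kstar_neighbors(beta), 2)

  # all-equal distances never break: lambda = c + 1/sqrt(n) > c
  beta_eq <- rep(0.7, 25)
  expect_equal(kstar_neighbors(beta_eq), 24L)

  expect_error(kstar_neighbors(numeric(0)), "empty")
  expect_error(kstar_neighbors(c(2, 1)), "ascending")
})

test_that("neighbor-count selection equals the literal oracle on fuzzed input", {
  set.seed(202)
  for (i in seq_len(1000)) {
    N <- sample(2:60, 1)
    beta <- sort(runif(N, 0, sample(c(0.5, 1, 3), 1)))
    if (i %% 7 == 0) beta <- rep(round(beta[1], 2), N)  # tie-heavy cases
    expect_identical(kstar_neighbors(beta), as.integer(kstar_oracle(beta)))
  }
})

test_that("weight smoothing solves the entropy-calibration equation", {
  # analytic case: distances (rho, rho+d, rho+d, rho+d)
  d <- 0.3
  w <- smooth_weights(c(0.2, 0.5, 0.5, 0.5))
  expect_equal(w, c(1, 1/3, 1/3, 1/3), tolerance = 1e-4)
  # the implied sigma is d / ln 3
  sigma <- -d / log(w[2])
  expect_equal(sigma, d / log(3), tolerance = 1e-4)

  # calibration property on random rows
  set.seed(33)
  for (i in 1:50) {
    k <- sample(2:20, 1)
    delta <- sort(runif(k, 0.05, 1))
    w <- smooth_weights(delta)
    expect_equal(sum(w), log2(k), tolerance = 1e-5)
    expect_true(all(w > 0 & w <= 1))
  }

  expect_equal(smooth_weights(0.4), 1.0)
  expect_error(smooth_weights(c(0.5, 0.1)), "ascending")
})

test_that("the cell network separates planted groups", {
  sp <- small_pipeline()
  g <- igraph::graph_from_adjacency_matrix(sp$net$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mod <- igraph::modularity(g, membership = sp$bm$truth$cell_type,
                            weights = igraph::E(g)$weight)
  expect_gt(mod, 0.5)
  expect_true(all(sp$net$neighbor_counts >= 1))
  expect_true(all(sp$net$weights@x > 0 & sp$net$weights@x <= 1))
  expect_equal(sum(Matrix::diag(sp$net$weights)), 0)
  expect_true(isSymmetric(sp$net$weights))
})

test_that("larger kappa never densifies the network", {
  sp <- small_pipeline()
  H <- normalize_encodings(sp$ml)
  n1 <- build_network(H, kappa = 1)
  n2 <- build_network(H, kappa = 2)
  expect_lte(length(n2$weights@x), length(n1$weights@x))
})

test_that("candidate retrieval in sqrt-space agrees with the exact backend", {
  set.seed(77)
  # 500 cells from a few distinct soft clusters
  centers <- matrix(rgamma(20 * 6, 0.5), 20, 6)
  H <- sapply(sample(1:6, 500, replace = TRUE), function(g)
    centers[, g] + rgamma(20, 0.3))
  H <- sweep(H, 2, colSums(H), "/")
  ne <- build_network(H, backend = "exact")
  na <- build_network(H, backend = "hellinger")
  Ee <- which(as.matrix(ne$weights) > 0)
  Ea <- which(as.matrix(na$weights) > 0)
  expect_gte(length(intersect(Ee, Ea)) / length(Ee), 0.9)
})

test_that("network construction rejects degenerate input", {
  expect_error(build_network(matrix(1, 3, 1)), "at least 2")
  expect_error(build_network(matrix(c(2, 1), 2, 2)), "column-stochastic")
})
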