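test_that("diffusion reaches the personalized-propagation fixed point", {
  # 4-node path graph with unit weights
  W <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(2, 3, 4), x = 1,
                            dims = c(4, 4), symmetric = TRUE)
  net <- structure(list(nodes = paste0("c", 1:4),
                        weights = as(W, "CsparseMatrix"), distances = W,
                        kappa = 1, neighbor_counts = rep(1L, 4)),
                   class = "cell_network")
  v <- c(1, 0, 0, 0)
  alpha <- 0.15
  x <- diffuse_values(net, v, alpha = alpha, tol = 1e-10)
  # dense linear-algebra oracle: x = alpha (I - (1-alpha) P)^{-1} v
  deg <- Matrix::rowSums(W)
  P <- as.matrix(W / deg)
  x_direct <- solve(diag(4) - (1 - alpha) * P, alpha * v)
  expect_equal(x, x_direct, tolerance = 1e-6)

  # constant input is a fixed point under row normalization
  expect_equal(diffuse_values(net, rep(2, 4)), rep(2, 4), tolerance = 1e-6)

  # alpha -> 1 returns the input
  expect_equal(diffuse_values(net, v, alpha = 0.999), v, tolerance = 1e-2)
  expect_error(diffuse_values(net, v, alpha = 1.5), "alpha")

  # column-stochastic rearrangement conserves total mass
  y <- diffuse_values(net, c(4, 0, 1, 0), alpha = 0.3, norm = "col")
  expect_equal(sum(y), 5, tolerance = 1e-8)
})

test_that("marker-based annotation recovers planted types", {
  sp <- small_pipeline()
  ct <- sp$bm$truth$cell_type
  # the generator's disjoint marker blocks, used as marker sets
  block <- floor(0.5 * 200 / 5)
  markers <- lapply(1:5, function(p) {
    marker_set(paste0("type", p),
               positive = paste0("gene_", ((p - 1) * block + 1):((p - 1) * block + 5)))
  })
  ann <- annotate_cells(sp$bm$expr, sp$net, markers, n_perm = 1000, seed = 1)
  acc <- mean(ann$labels == paste0("type", ct))
  expect_gte(acc, 0.95)
  expect_true(all(is.finite(ann$zscores)))

  # doubling the permutations barely moves the z-scores (stable null)
  ann2 <- annotate_cells(sp$bm$expr, sp$net, markers, n_perm = 2000, seed = 1)
  expect_lt(max(abs(ann2$zscores - ann$zscores)), 0.5)
})

test_that("marker sets reject sign conflicts and handle missing genes", {
  expect_error(marker_set("bad", positive = "CD3E", negative = "CD3E"),
               "both positive and negative")
  expect_error(marker_set("empty"), "no markers")

  sp <- small_pipeline()
  ms <- marker_set("with_missing", positive = c("gene_1", "nonexistent"))
  expect_warning(annotate_cells(sp$bm$expr, sp$net, list(ms), n_perm = 50),
                 "missing")
  ms_gone <- marker_set("all_missing", positive = "nope")
  expect_error(suppressWarnings(
    annotate_cells(sp$bm$expr, sp$net, list(ms_gone), n_perm = 50)),
    "no usable")
})

test_that("label propagation fills gaps and respects consistent labelings", {
  sp <- small_pipeline()
  ct <- paste0("type", sp$bm$truth$cell_type)

  # fully consistent labeling is a fixed point
  out_full <- propagate_labels(sp$net, ct)
  expect_identical(unname(out_full$labels), ct)

  # a single unlabeled cell adopts its neighbors' label
  one <- ct; one[13] <- NA
  out_one <- propagate_labels(sp$net, one)
  expect_identical(unname(out_one$labels[13]), ct[13])

  # 50% masking: planted labels recovered for at least 90% of masked cells
  masked <- ct
  hide <- statescape:::with_seed(5, sample(length(ct), length(ct) / 2))
  masked[hide] <- NA
  out <- propagate_labels(sp$net, masked)
  expect_gte(mean(out$labels[hide] == ct[hide], na.rm = TRUE), 0.9)
  # no label outside the input label set
  expect_true(all(out$labels %in% unique(ct)))

  expect_error(propagate_labels(sp$net, rep(NA_character_, length(ct))),
               "at least one")
})

test_that("state footprints live on the right cells", {
  sp <- small_pipeline()
  states <- prune_multilevel(sp$ml)
  rp <- evaluate_recovery(states, sp$bm$truth)
  ct <- sp$bm$truth$cell_type
  for (p in which(rp$matched)) {
    f <- footprint(states, rp$state[p])
    expect_gt(mean(f[ct == p]), mean(f[ct != p]))
  }
  # per-cell sum of all rows is bounded after level renormalization
  L <- states$n_levels
  expect_true(all(colSums(states$H_mr) / L <= 1 + 1e-8))
  expect_error(footprint(states, nrow(states$H_mr) + 1), "out of range")

  # diffusion smoothing keeps the footprint aligned
  f_s <- footprint(states, rp$state[1], net = sp$net)
  expect_gt(cor(f_s, footprint(states, rp$state[1])), 0.5)
})

test_that("state enrichment scores behave under permutation nulls", {
  sp <- small_pipeline()
  states <- prune_multilevel(sp$ml)
  ct <- factor(paste0("type", sp$bm$truth$cell_type))

  # constant values are permutation-invariant
  z0 <- state_enrichment(states, rep(3.7, length(ct)), n_perm = 200, seed = 2)
  expect_true(all(abs(z0) < 1e-8))

  # planted labels dominate the diagonal under the recovered matching
  z <- state_enrichment(states, ct, n_perm = 500, seed = 2)
  rp <- evaluate_recovery(states, sp$bm$truth)
  diag_z <- z[cbind(rp$state[rp$matched], which(rp$matched))]
  expect_true(all(diag_z > 3))
  off <- z[rp$state[rp$matched], ]
  off[cbind(seq_len(nrow(off)), which(rp$matched))] <- NA
  expect_gt(mean(diag_z), mean(abs(off), na.rm = TRUE))

  # shuffling the values destroys enrichment
  z_sh <- state_enrichment(states,
                           statescape:::with_seed(8, sample(as.character(ct))),
                           n_perm = 1000, seed = 3)
  expect_lt(max(abs(z_sh)), 3)
  expect_error(state_enrichment(states, ct[-1]), "length")
})

test_that("network clustering recovers planted groups deterministically", {
  sp <- small_pipeline()
  cl <- cluster_network(sp$net, resolution = 1, seed = 3)
  expect_gt(ari(cl, sp$bm$truth$cell_type), 0.9)
  expect_identical(cl, cluster_network(sp$net, resolution = 1, seed = 3))

  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(sp$net$weights, mode = "undirected",
                                        weighted = TRUE))$membership
  cl0 <- cluster_network(sp$net, resolution = 1e-4, seed = 3)
  expect_lte(length(unique(cl0)), length(unique(comp)))
})
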