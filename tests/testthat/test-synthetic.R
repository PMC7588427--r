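test_that("the benchmark generator produces the configured ground truth", {
  cfg <- synthetic_config(seed = 3)
  bm <- generate_benchmark(cfg)
  expect_equal(nrow(bm$truth$program_loadings), 14)   # 13 identity + 1 activity
  expect_equal(ncol(bm$expr$values), 13 * 50)
  expect_equal(bm$truth$program_type,
               rep(c("identity", "activity"), c(13, 1)))
  # identity loadings one-hot per cell
  ident <- bm$truth$program_loadings[1:13, ]
  expect_true(all(colSums(ident) == 1))
  expect_true(all(ident %in% c(0, 1)))
  # activity loadings form a gradient over several types
  act <- bm$truth$program_loadings[14, ]
  expect_true(all(act >= 0 & act <= 1))
  affected <- unique(bm$truth$cell_type[act > 0])
  expect_gte(length(affected), 2)
  expect_gt(length(unique(act[act > 0])), 10)

  # reproducibility
  bm2 <- generate_benchmark(cfg)
  expect_identical(as.matrix(bm$expr$values), as.matrix(bm2$expr$values))

  expect_error(generate_benchmark(synthetic_config(n_genes = 60, seed = 1)),
               "config error")
})

test_that("low noise keeps cells of a type more similar than across types", {
  bm <- generate_benchmark(synthetic_config(n_identity_programs = 4,
                                            n_activity_programs = 0,
                                            cells_per_type = 15,
                                            n_genes = 200, seed = 6))
  X <- log1p(as.matrix(bm$expr$values))
  ct <- bm$truth$cell_type
  cors <- cor(X)
  same <- outer(ct, ct, "==") & upper.tri(cors)
  diff <- outer(ct, ct, "!=") & upper.tri(cors)
  expect_gt(mean(cors[same]), mean(cors[diff]))
})

test_that("hull fixtures plant recoverable vertices", {
  hf <- hull_fixture(D = 2, k = 3, n_cells = 40, seed = 2)
  V <- hf$S_r[, 1:3]
  # barycentric feasibility: every cell inside the triangle
  for (j in 4:40) {
    w <- solve(rbind(V, 1), c(hf$S_r[, j], 1))
    expect_true(all(w > -1e-8))
  }
  # recovery needs linearly independent vertices, hence D >= k
  hf4 <- hull_fixture(D = 4, k = 3, n_cells = 50, seed = 8)
  V4 <- hf4$S_r[, attr(hf4, "planted")]
  fit <- run_archetypes(hf4, 3)
  cosim <- sapply(1:3, function(j)
    max(abs(crossprod(fit$W[, j], V4)) /
          (sqrt(sum(fit$W[, j]^2)) * sqrt(colSums(V4^2)))))
  expect_true(all(cosim > 0.999))

  hf1 <- hull_fixture(D = 3, k = 1, n_cells = 10, seed = 4)
  expect_true(all(apply(hf1$S_r, 2, function(x) all(x == hf1$S_r[, 1]))))
  expect_error(hull_fixture(D = 2, k = 5, n_cells = 3), "exceed")
})

test_that("the capture-rate statistic agrees with the reference Welch test", {
  set.seed(44)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, 0, 2))
    y <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 2))
    ours <- statescape:::welch_score(x, y)
    ref <- -log10(t.test(x, y, alternative = "greater")$p.value)
    expect_equal(ours, ref, tolerance = 1e-8)
  }
})

test_that("the assignment solver is optimal on exhaustively checked instances", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(3:5, 1); m <- sample(2:n, 1)
    S <- matrix(runif(n * m), n, m)
    sol <- statescape:::solve_assignment(max(S) - S)
    got <- sum(S[cbind(sol, seq_len(m))])
    # brute force over all injections of columns into rows
    best <- 0
    perms <- combn(n, m, simplify = FALSE)
    for (rows in perms) {
      pm <- if (m <= 1) list(1) else
        unlist(lapply(seq_len(factorial(m)), function(z) NULL))
      # enumerate permutations of the chosen rows
      allp <- function(v) if (length(v) <= 1) list(v) else
        do.call(c, lapply(seq_along(v), function(z)
          lapply(allp(v[-z]), function(r) c(v[z], r))))
      for (ord in allp(rows)) best <- max(best, sum(S[cbind(ord, seq_len(m))]))
    }
    expect_equal(got, best, tolerance = 1e-10)
  }
})

test_that("recovery evaluation self-matches and collapses under shuffling", {
  bm <- generate_benchmark(synthetic_config(seed = 9))
  truth <- bm$truth
  # states built from the truth itself: perfect match, purity 1
  perfect <- structure(list(H_mr = truth$program_loadings,
                            W_mr = truth$program_signatures,
                            selected = data.frame(k = rep(14, 14))),
                       class = "multires_states")
  rp <- evaluate_recovery(perfect, truth)
  expect_equal(attr(rp, "n_matched"), 14)
  expect_true(all(rp$purity[rp$matched] > 0.999))

  # shuffled encodings: the matching collapses
  shuffled <- perfect
  shuffled$H_mr <- truth$program_loadings[, statescape:::with_seed(1,
                                            sample(ncol(truth$program_loadings)))]
  rp_sh <- evaluate_recovery(shuffled, truth)
  expect_lt(median(rp_sh$score), 2)
})
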