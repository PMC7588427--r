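test_that("successive projection follows the hand-executed selection order", {
  X <- cbind(c(2, 0), c(0, 1), c(0.5, 0.5))
  # max norm picks (2,0); after projecting it out, (0,1) has the largest residual
  expect_identical(spa_select(X, 2), c(1L, 2L))

  # k = 1 is the maximum-norm column
  set.seed(1)
  Y <- matrix(rnorm(4 * 30), 4, 30)
  expect_identical(spa_select(Y, 1), which.max(colSums(Y^2)))

  # duplicated columns are deflated, so no duplicate indices are returned
  Z <- cbind(c(1, 2, 0), c(1, 2, 0), c(3, 0, 1), c(3, 0, 1), c(0, 4, 2))
  sel <- spa_select(Z, 3)
  expect_identical(sort(unique(sel)), sort(sel))
})

test_that("successive projection signals rank-deficient input", {
  X <- matrix(rnorm(6), 2, 3) # rank 2
  X <- cbind(X, X %*% matrix(runif(9), 3, 3)) # still rank 2
  expect_error(spa_select(X, 4), "rank-deficient")
})

test_that("archetypal refinement recovers planted hull vertices", {
  hf <- hull_fixture(D = 5, k = 4, n_cells = 80, seed = 3)
  fit <- run_archetypes(hf, 4)
  obj <- fit$objective_trace
  expect_lt(obj[length(obj)] / sum(hf$S_r^2), 1e-6)
  V <- hf$S_r[, attr(hf, "planted")]
  cosim <- sapply(seq_len(4), function(j) {
    max(abs(crossprod(fit$W[, j], V)) /
          (sqrt(sum(fit$W[, j]^2)) * sqrt(colSums(V^2))))
  })
  expect_true(all(cosim > 0.999))
})

test_that("single-archetype refinement forces an all-ones encoding", {
  hf <- hull_fixture(D = 3, k = 2, n_cells = 20, seed = 5)
  fit <- run_archetypes(hf, 1)
  expect_equal(unname(fit$H), matrix(1, 1, 20))
  expect_equal(unname(fit$W), unname(hf$S_r %*% fit$C), tolerance = 1e-12)
})

test_that("alternating refinement is monotone and simplex-feasible", {
  set.seed(8)
  S <- matrix(rnorm(10 * 100), 10, 100)
  fit <- aa_refine(S, spa_select(S, 4))
  # recomputed residuals confirm the recorded trace
  expect_equal(fit$objective_trace[length(fit$objective_trace)],
               sum((S - fit$W %*% fit$H)^2), tolerance = 1e-8)
  expect_true(all(diff(fit$objective_trace) <= 1e-9))
  expect_true(all(abs(colSums(fit$C) - 1) < 1e-8))
  expect_true(all(abs(colSums(fit$H) - 1) < 1e-8))
  expect_gte(min(fit$C), 0)
  expect_gte(min(fit$H), 0)
  # archetypes are convex combinations of cells by construction
  expect_equal(unname(fit$W), unname(S %*% fit$C), tolerance = 1e-10)
})

test_that("refinement validates its inputs", {
  S <- matrix(rnorm(20), 4, 5)
  Sbad <- S; Sbad[2, 2] <- NaN
  expect_error(aa_refine(Sbad, 1L), "non-finite")
  expect_error(aa_refine(S, 1:6), "exceed")
})

test_that("decomposition runs are bitwise reproducible", {
  hf <- noisy_hull()
  f1 <- run_archetypes(hf, 5)
  f2 <- run_archetypes(hf, 5)
  expect_identical(f1$C, f2$C)
  expect_identical(f1$H, f2$H)
})

test_that("surplus archetypes beyond the supported states stay trivial", {
  # 5 planted states with overdispersed counts: once k far exceeds the
  # state count, surplus archetypes park on single outlying cells
  sp <- small_pipeline()
  fit <- run_archetypes(sp$red, 12)
  nontrivial <- sum(colSums(fit$C > 1e-5) > 1)
  expect_lte(nontrivial, 2 * 5)
  expect_gte(12 - nontrivial, 2)   # at least some columns stayed single-cell
})

test_that("tiny instances agree with a brute-force simplex grid search", {
  set.seed(13)
  S <- matrix(rnorm(12, sd = 2), 2, 6) + 0.2 * matrix(rnorm(12), 2, 6)
  fit <- run_archetypes(S, 2)
  solver_obj <- fit$objective_trace[length(fit$objective_trace)]

  # enumerate C columns on a step-0.25 simplex grid, H on a fine 1D grid
  comps <- expand.grid(rep(list(0:4), 6))
  comps <- as.matrix(comps[rowSums(comps) == 4, ]) / 4
  hgrid <- seq(0, 1, by = 0.02)
  best <- Inf
  for (a in seq_len(nrow(comps))) {
    w1 <- S %*% comps[a, ]
    for (b in seq_len(nrow(comps))) {
      W <- cbind(w1, S %*% comps[b, ])
      A <- W[, 1] - W[, 2]
      # per-cell best h: residual ||s - W2 - h (W1 - W2)||^2 over grid
      R0 <- S - W[, 2]
      e1 <- colSums(R0^2)
      e2 <- colSums(R0 * A)
      e3 <- sum(A^2)
      obj <- sum(vapply(seq_len(6), function(i)
        min(e1[i] - 2 * hgrid * e2[i] + hgrid^2 * e3), numeric(1)))
      if (obj < best) best <- obj
    }
  }
  expect_lte(solver_obj, best + 1e-4)
})
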