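#' Successive projection selection of prototype cells
#'
#' Separable-NMF initialization: iteratively picks the cell column of maximum
#' residual Euclidean norm and projects all columns onto the orthogonal
#' complement of the picked column. The selected cells are extreme
#' ("prototype") cells that seed the archetypal refinement. The procedure is
#' fully deterministic; exact norm ties are broken by the lowest column index.
#'
#' @param S_r a [reduced_profile()] (or bare D x cells matrix).
#' @param k number of prototypes to select, `1 <= k <= cells`.
#' @return Integer vector of `k` distinct cell column indices, in selection
#'   order.
#' @export
spa_select <- function(S_r, k) {
  X <- if (inherits(S_r, "reduced_profile")) S_r$S_r else as.matrix(S_r)
  n <- ncol(X)
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= number of cells")
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite entries in profile")

  R <- X
  norms2 <- colSums(R^2)
  scale0 <- max(norms2)
  sel <- integer(k)
  for (t in seq_len(k)) {
    j <- which.max(norms2)               # first max: lowest index on ties
    if (norms2[j] <= scale0 * 1e-20) {
      stop("rank-deficient input: residual vanished after selecting indices ",
           paste(sel[seq_len(t - 1)], collapse = ", "))
    }
    sel[t] <- j
    u <- R[, j] / sqrt(norms2[j])
    R <- R - u %*% crossprod(u, R)       # deflate the picked direction
    norms2 <- pmax(colSums(R^2), 0)
  }
  sel
}

#' Archetypal refinement by alternating simplex-constrained least squares
#'
#' Refines SPA-selected prototypes into archetypes solving
#' `min ||S - (S C) H||_F^2` with every column of `C` and of `H` constrained
#' to the probability simplex. With `W = S C` fixed, each column of `H` is an
#' exact simplex-constrained least-squares problem; columns of `C` are then
#' updated by block coordinate descent, each again an exact simplex-constrained
#' problem, so the objective is non-increasing by construction. Iteration
#' stops when the relative objective change drops below `tol` or after
#' `max_iter` alternations.
#'
#' Columns whose archetype receives (numerically) no encoding mass are left
#' untouched, so surplus archetypes keep their single-cell SPA initialization;
#' this is the mechanism behind the saturation analysis.
#'
#' @param S_r a [reduced_profile()] (or bare D x cells matrix).
#' @param init_indices prototype cell indices (from [spa_select()]).
#' @param max_iter maximum alternations (default 100).
#' @param tol relative objective-change tolerance (default 1e-6).
#' @return An object of class `archetype_fit` with elements `k`, `C`
#'   (cells x k), `H` (k x cells), `W = S_r C` (D x k), `selected_indices`,
#'   and the per-iteration `objective_trace`.
#' @export
aa_refine <- function(S_r, init_indices, max_iter = 100, tol = 1e-6) {
  S <- if (inherits(S_r, "reduced_profile")) S_r$S_r else as.matrix(S_r)
  if (anyNA(S) || any(!is.finite(S))) stop("non-finite entries in profile")
  n <- ncol(S)
  k <- length(init_indices)
  if (max_iter < 1) stop("max_iter must be at least 1")
  if (k > n) stop("k cannot exceed the number of cells")
  if (any(init_indices < 1 | init_indices > n)) stop("init index out of range")

  C <- matrix(0, n, k)
  C[cbind(init_indices, seq_len(k))] <- 1
  W <- S[, init_indices, drop = FALSE]
  H <- cpp_simplex_ls(W, S)
  obj <- sum((S - W %*% H)^2)
  trace <- obj

  for (iter in seq_len(max_iter)) {
    C_prev <- C; H_prev <- H; W_prev <- W
    # C update: block coordinate descent over archetype columns
    R <- S - W %*% H
    for (j in seq_len(k)) {
      hj <- H[j, ]
      n2 <- sum(hj^2)
      if (n2 < 1e-12) next               # unused archetype: leave unchanged
      target <- (R %*% hj) / n2 + W[, j]
      cj <- drop(cpp_simplex_ls(S, matrix(target, ncol = 1)))
      w_new <- drop(S %*% cj)
      R <- R - (w_new - W[, j]) %*% t(hj)
      C[, j] <- cj
      W[, j] <- w_new
    }
    # H update: exact per-cell simplex least squares
    H <- cpp_simplex_ls(W, S)
    obj_new <- sum((S - W %*% H)^2)
    if (obj_new > obj * (1 + 1e-12) + 1e-12) {
      # numerical safeguard: keep the previous (better) factors
      C <- C_prev; H <- H_prev; W <- W_prev
      break
    }
    trace <- c(trace, obj_new)
    converged <- (obj - obj_new) <= tol * max(obj, .Machine$double.eps)
    obj <- obj_new
    if (converged) break
  }

  structure(list(k = k, C = C, H = H, W = W,
                 selected_indices = init_indices,
                 objective_trace = trace),
            class = "archetype_fit")
}

#' Single-level archetypal decomposition
#'
#' Runs [spa_select()] followed by [aa_refine()]. The composition contains no
#' randomness, so repeated runs are bitwise identical.
#'
#' @inheritParams aa_refine
#' @param k number of archetypes.
#' @return An `archetype_fit` (see [aa_refine()]).
#' @export
run_archetypes <- function(S_r, k, max_iter = 100, tol = 1e-6) {
  aa_refine(S_r, spa_select(S_r, k), max_iter = max_iter, tol = tol)
}
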