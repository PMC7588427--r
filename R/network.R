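#' Column-stochastic normalization of multilevel encodings
#'
#' Rescales each column of the multilevel encoding matrix `H_star` to sum to
#' one so it can be treated as a distribution over patterns. Because every
#' level block of `H_star` is already column-stochastic, this equals dividing
#' by the number of levels.
#'
#' @param x a `multilevel_fit` or a non-negative matrix with patterns in rows
#'   and cells in columns.
#' @return A column-stochastic matrix of the same shape.
#' @export
normalize_encodings <- function(x) {
  H <- if (inherits(x, "multilevel_fit")) x$H_star else as.matrix(x)
  if (min(H) < 0) stop("encodings must be non-negative")
  cs <- colSums(H)
  if (any(cs == 0)) stop("zero encoding column(s): ",
                         paste(which(cs == 0), collapse = ", "))
  sweep(H, 2, cs, "/")
}

#' Jensen-Shannon metric distance between two distributions
#'
#' The square root of the Jensen-Shannon divergence
#' `JS(p, q) = (KL(p || m) + KL(q || m)) / 2`, `m = (p + q)/2`, computed with
#' base-2 logarithms so the divergence (and hence the distance) is bounded in
#' `[0, 1]`. The square root, unlike the divergence itself, satisfies the
#' triangle inequality, giving a true metric on the cell-state encodings.
#' The `0 * log(0/x) = 0` convention applies.
#'
#' @param p,q non-negative vectors of equal length summing to 1 (within 1e-6).
#' @return The metric distance, a scalar in `[0, 1]`.
#' @export
jsd_distance <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch")
  if (min(p) < 0 || min(q) < 0) stop("negative entries")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("inputs must sum to 1")
  m <- (p + q) / 2
  js <- -sum(xlog2x(m)) + (sum(xlog2x(p)) + sum(xlog2x(q))) / 2
  sqrt(min(max(js, 0), 1))
}

# distances from column j of a column-stochastic matrix H to all columns,
# via JS(p, q) = H2(m) - (H2(p) + H2(q))/2 with H2 the base-2 entropy
jsd_to_all <- function(H, j, ent = NULL) {
  if (is.null(ent)) ent <- -colSums(xlog2x(H))
  M <- (H + H[, j]) / 2
  entM <- -colSums(xlog2x(M))
  sqrt(pmin(pmax(entM - (ent + ent[j]) / 2, 0), 1))
}

#' Density-adaptive neighbor count selection
#'
#' Given the ascending vector `beta` of (sparsity-scaled) candidate-neighbor
#' distances of one cell, picks the per-cell neighbor count by the k*-NN rule:
#' starting from `lambda_1 = beta_1 + 1`, the running threshold
#' `lambda_{n+1} = (sum(beta_1..n) + sqrt(n + sum^2 - n * sumsq)) / n`
#' is tracked and the first `n` with `lambda_n <= beta_n` is returned. When
#' the loop never breaks (e.g. all candidates equidistant, where
#' `lambda = beta + 1/sqrt(n)` stays above `beta`), `N - 1` is returned.
#'
#' @param beta ascending numeric vector of candidate distances (already scaled
#'   by the sparsity parameter `kappa`).
#' @return The selected neighbor count `n_opt` (an integer).
#' @export
kstar_neighbors <- function(beta) {
  N <- length(beta)
  if (N == 0) stop("empty distance vector")
  if (is.unsorted(beta)) stop("beta must be ascending")
  if (N == 1) return(0L)
  s1 <- cumsum(beta)
  s2 <- cumsum(beta^2)
  lam <- numeric(N - 1)
  lam[1] <- beta[1] + 1
  if (N > 2) {
    n <- seq_len(N - 2)
    lam[n + 1] <- (s1[n] + sqrt(pmax(n + s1[n]^2 - n * s2[n], 0))) / n
  }
  hit <- which(lam <= beta[seq_len(N - 1)])
  if (length(hit)) hit[1] else N - 1L
}

#' Neighborhood weight smoothing
#'
#' Converts one cell's ascending neighbor distances into affinities
#' `w_j = exp(-(delta_j - rho) / sigma)` where `rho` is the closest distance
#' and `sigma` solves `sum_j w_j = log2(k)` (bisection to 1e-5). With a single
#' neighbor the target `log2(1) = 0` is unattainable and the convention is a
#' weight of 1. If all distances tie with `rho`, every affinity is 1.
#'
#' @param delta ascending distances of the kept neighbors.
#' @param tol bisection tolerance on the weight sum (default 1e-5).
#' @return Affinity vector in `(0, 1]`, same length as `delta`.
#' @export
smooth_weights <- function(delta, tol = 1e-5) {
  k <- length(delta)
  if (k == 0) stop("empty distance vector")
  if (is.unsorted(delta)) stop("distances must be ascending")
  if (k == 1) return(1.0)
  rho <- delta[1]
  d <- delta - rho
  if (max(d) < 1e-15) return(rep(1.0, k))
  target <- log2(k)
  f <- function(sigma) sum(exp(-d / sigma))
  lo <- 1e-10
  hi <- 10 * max(d)
  if (f(lo) >= target) return(pmax(exp(-d / lo), 1e-8))
  it <- 0
  while (f(hi) < target && it < 60) { hi <- hi * 2; it <- it + 1 }
  for (i in seq_len(64)) {
    mid <- (lo + hi) / 2
    if (abs(f(mid) - target) < tol) { lo <- hi <- mid; break }
    if (f(mid) < target) lo <- mid else hi <- mid
  }
  # floor keeps affinities strictly positive when the target pins a weight
  # to the numerical zero of the exponential
  pmax(exp(-d / ((lo + hi) / 2)), 1e-8)
}

#' Build the density-adaptive cell-state network
#'
#' Constructs the sparse weighted cell network from column-stochastic
#' multilevel encodings: per cell, a candidate neighbor pool is retrieved,
#' re-ranked by the exact Jensen-Shannon metric, trimmed by the per-cell
#' k*-NN rule on `kappa`-scaled distances ([kstar_neighbors()]), and the kept
#' distances are converted to affinities by [smooth_weights()]. The directed
#' graph is symmetrized by keeping `max(w_ij, w_ji)`, which preserves the
#' density-adaptive reach of sparse neighborhoods.
#'
#' @param x a `multilevel_fit`, or a column-stochastic encoding matrix
#'   (patterns x cells).
#' @param kappa sparsity parameter scaling distances before neighbor-count
#'   selection; larger values give sparser networks (default 1: distances are
#'   used unscaled).
#' @param backend `"exact"` computes exact metric distances to all cells;
#'   `"hellinger"` retrieves candidates by Euclidean distance between
#'   square-rooted encodings (a metric-compatible embedding computed with one
#'   BLAS cross-product) and re-ranks only the candidates with the exact
#'   metric.
#' @param candidates candidate pool size per cell before k*-NN trimming;
#'   default `min(N - 1, max(30, ceiling(sqrt(N))))`.
#' @return An object of class `cell_network` with fields `nodes`, `weights`
#'   (sparse symmetric affinities in `(0, 1]`), `distances` (metric distances
#'   on kept edges), `kappa`, and per-cell `neighbor_counts`.
#' @export
build_network <- function(x, kappa = 1.0, backend = c("exact", "hellinger"),
                          candidates = NULL) {
  backend <- match.arg(backend)
  H <- if (inherits(x, "multilevel_fit")) normalize_encodings(x) else as.matrix(x)
  n <- ncol(H)
  if (n < 2) stop("need at least 2 cells to build a network")
  if (any(abs(colSums(H) - 1) > 1e-6))
    stop("encodings must be column-stochastic; see normalize_encodings()")
  nodes <- colnames(H) %||% paste0("cell_", seq_len(n))

  cand <- candidates %||% min(n - 1, max(30, ceiling(sqrt(n))))
  cand <- max(1L, min(as.integer(cand), n - 1L))

  ent <- -colSums(xlog2x(H))
  G <- NULL
  if (backend == "hellinger") {
    Q <- sqrt(H)
    G <- crossprod(Q)                    # cos-type similarities in sqrt space
  }

  ii <- jj <- integer(0)
  ww <- dd <- numeric(0)
  n_opt_all <- integer(n)
  for (i in seq_len(n)) {
    if (backend == "exact") {
      delta <- jsd_to_all(H, i, ent)
      delta[i] <- Inf
      ord <- order(delta)[seq_len(cand)]
    } else {
      hell <- sqrt(pmax(2 - 2 * G[, i], 0))
      hell[i] <- Inf
      pool <- order(hell)[seq_len(min(2L * cand, n - 1L))]
      dpool <- vapply(pool, function(j) jsd_distance(H[, i], H[, j]), numeric(1))
      keep <- order(dpool)[seq_len(cand)]
      ord <- pool[keep]
      delta <- rep(Inf, n)
      delta[ord] <- dpool[keep]
    }
    dsort <- delta[ord]
    n_opt <- kstar_neighbors(kappa * dsort)
    n_opt <- max(1L, min(n_opt, length(ord)))
    n_opt_all[i] <- n_opt
    nb <- ord[seq_len(n_opt)]
    w <- smooth_weights(dsort[seq_len(n_opt)])
    ii <- c(ii, rep.int(i, n_opt)); jj <- c(jj, nb)
    ww <- c(ww, w); dd <- c(dd, dsort[seq_len(n_opt)])
  }

  Wd <- sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  Dd <- sparseMatrix(i = ii, j = jj, x = dd, dims = c(n, n))
  # elementwise max symmetrization
  Ws <- (Wd + t(Wd) + abs(Wd - t(Wd))) / 2
  Ds <- (Dd + t(Dd) + abs(Dd - t(Dd))) / 2
  diag(Ws) <- 0; diag(Ds) <- 0
  Ws <- drop0(Ws); Ds <- drop0(Ds)
  dimnames(Ws) <- dimnames(Ds) <- list(nodes, nodes)

  structure(list(nodes = nodes, weights = Ws, distances = Ds,
                 kappa = kappa, neighbor_counts = n_opt_all),
            class = "cell_network")
}

# igraph view of a cell_network (weighted, undirected)
network_graph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}
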