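#' Embedding kernel parameters from a compactness value
#'
#' The low-dimensional kernel `f(d) = 1 / (1 + a d^(2b))` is parameterized by
#' a single `compactness` value in `[0, 100]`. Compactness is mapped
#' monotonically (strictly decreasing) to a min-dist-like spread value, and
#' `(a, b)` are then fitted by nonlinear least squares to the smooth-step
#' target curve (1 below the spread value, exponential decay beyond it).
#'
#' @param compactness integer in `[0, 100]`; larger values give tighter
#'   clusters in the embedding.
#' @return Named numeric vector `c(a, b)` with the fitted spread value in
#'   attribute `"spread_value"`.
#' @export
fit_ab <- function(compactness) {
  if (length(compactness) != 1 || is.na(compactness) ||
      compactness < 0 || compactness > 100)
    stop("compactness must be a single value in [0, 100]")
  # strictly decreasing, log-spaced: 0.99 at compactness 0 down to 0.01 at 100
  md <- 0.99 * (0.01 / 0.99)^(compactness / 100)
  d <- seq(0, 3, length.out = 300)
  y <- ifelse(d < md, 1, exp(-(d - md)))
  fit <- minpack.lm::nlsLM(y ~ 1 / (1 + a * d^(2 * b)),
                           start = list(a = 1.577, b = 0.895),
                           lower = c(1e-3, 0.1), upper = c(1e4, 5),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  out <- stats::coef(fit)
  names(out) <- c("a", "b")
  attr(out, "spread_value") <- md
  out
}

#' Embed the cell network in 2D or 3D
#'
#' Lays out the cell network by stochastic gradient descent on the fuzzy
#' cross-entropy between the network's smoothed edge affinities and the
#' embedding kernel `f(d) = 1/(1 + a d^(2b))`: per-edge attractive updates
#' (sampled proportionally to edge weight) and uniformly sampled repulsive
#' updates. Initialization is a seeded spectral layout of the normalized
#' network adjacency, so results are reproducible for a fixed seed (single
#' worker).
#'
#' @param net a [build_network()] result.
#' @param dims 2 or 3.
#' @param compactness see [fit_ab()].
#' @param epochs SGD epochs (default 500).
#' @param seed integer seed.
#' @param negative_rate repulsive samples per attractive update (default 5).
#' @param learning_rate initial step size, linearly decayed to 0 (default 1).
#' @return An object of class `state_embedding` with `coords` (cells x dims),
#'   the kernel parameters `a`, `b`, `compactness`, and `seed`.
#' @export
embed_network <- function(net, dims = 2, compactness = 50, epochs = 500,
                          seed = 0, negative_rate = 5, learning_rate = 1.0) {
  stopifnot(inherits(net, "cell_network"))
  if (!dims %in% c(2, 3)) stop("dims must be 2 or 3")
  W <- net$weights
  n <- length(net$nodes)
  if (n == 0 || length(W@x) == 0) stop("empty network")

  ab <- fit_ab(compactness)

  # spectral initialization: top eigenvectors of the symmetrically
  # normalized adjacency (excluding the trivial stationary component)
  deg <- Matrix::rowSums(W)
  dsq <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  A <- as.matrix(Diagonal(x = dsq) %*% W %*% Diagonal(x = dsq))
  ev <- eigen(A, symmetric = TRUE)
  init <- ev$vectors[, seq(2, dims + 1), drop = FALSE]
  init <- apply(init, 2, function(v) {
    r <- max(v) - min(v)
    if (r < 1e-12) v else 10 * (v - min(v)) / r - 5
  })
  init <- init + with_seed(seed, matrix(rnorm(n * dims, sd = 1e-3), n, dims))

  # directed edge list (both orientations), as sampled by the SGD schedule
  Wt <- as(as(W, "generalMatrix"), "TsparseMatrix")
  keep <- Wt@x > 0
  head <- Wt@i[keep]; tail <- Wt@j[keep]; wts <- Wt@x[keep]

  coords <- cpp_layout_sgd(init, head, tail, wts, ab[["a"]], ab[["b"]],
                           as.integer(epochs), learning_rate,
                           as.integer(negative_rate), as.integer(seed))
  rownames(coords) <- net$nodes
  structure(list(coords = coords, a = ab[["a"]], b = ab[["b"]],
                 compactness = as.integer(compactness), seed = seed,
                 dims = dims),
            class = "state_embedding")
}

#' Cross-entropy layout objective on an edge sample
#'
#' Evaluates the fuzzy cross-entropy
#' `sum w log(w / f(d)) + (1 - w) log((1 - w) / f(1 - d))` over a set of
#' edges, with `f` the embedding kernel. Used to monitor that optimization
#' improves the objective from its initialization.
#'
#' @param coords cells x dims coordinate matrix.
#' @param head,tail 1-based endpoint indices of the sampled edges.
#' @param w edge affinities in `(0, 1]`.
#' @param a,b kernel parameters.
#' @return The objective value (a scalar).
#' @export
layout_objective <- function(coords, head, tail, w, a, b) {
  d <- sqrt(rowSums((coords[head, , drop = FALSE] -
                     coords[tail, , drop = FALSE])^2))
  f <- function(x) 1 / (1 + a * pmax(x, 0)^(2 * b))
  eps <- 1e-9
  fd <- pmin(pmax(f(d), eps), 1 - eps)
  fr <- pmin(pmax(f(1 - d), eps), 1 - eps)
  w <- pmin(pmax(w, eps), 1 - eps)
  sum(w * log(w / fd) + (1 - w) * log((1 - w) / fr))
}

#' De novo cell coloring from a 3D embedding
#'
#' Maps 3D embedding coordinates into the perceptually uniform CIELAB color
#' space so that cells close in the embedding receive perceptually close
#' colors. The coordinate axis with the largest variance drives lightness
#' (`L* in [35, 85]`); the remaining two axes map to `a*, b* in [-40, 40]`.
#' All three axes share one scale factor (the largest that keeps the cloud in
#' the in-gamut box), so the mapping is a similarity transform and CIELAB
#' distances remain proportional to 3D distances. Colors are converted to
#' sRGB and clipped to `[0, 1]`; degenerate (zero-variance) inputs map to the
#' box center, so coincident coordinates yield a single uniform color.
#'
#' @param embedding3d a `state_embedding` with `dims = 3`.
#' @return cells x 3 matrix of sRGB values in `[0, 1]`, with the CIELAB
#'   coordinates in attribute `"lab"` and hex strings in attribute `"hex"`.
#' @export
denovo_colors <- function(embedding3d) {
  stopifnot(inherits(embedding3d, "state_embedding"))
  if (embedding3d$dims != 3) stop("de novo coloring requires a 3D embedding")
  X <- embedding3d$coords
  vars <- apply(X, 2, var)
  ord <- order(vars, decreasing = TRUE)   # largest-variance axis -> L*
  X <- X[, ord, drop = FALSE]

  # one common scale factor keeps the mapping a similarity transform, so
  # CIELAB distances stay proportional to 3D distances (up to clipping)
  dev <- sweep(X, 2, colMeans(X))
  half <- c(25, 40, 40)                   # L* in [35,85], a*/b* in [-40,40]
  lims <- apply(abs(dev), 2, max)
  s <- if (all(lims < 1e-12)) 0 else min(half[lims > 1e-12] / lims[lims > 1e-12])
  lab <- cbind(L = 60 + s * dev[, 1],
               a = 0 + s * dev[, 2],
               b = 0 + s * dev[, 3])
  srgb <- convertColor(lab, from = "Lab", to = "sRGB", clip = TRUE)
  srgb <- pmin(pmax(srgb, 0), 1)
  rownames(srgb) <- rownames(embedding3d$coords)
  colnames(srgb) <- c("r", "g", "b")
  attr(srgb, "lab") <- lab
  attr(srgb, "hex") <- rgb(srgb[, 1], srgb[, 2], srgb[, 3])
  srgb
}
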