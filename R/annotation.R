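#' Network diffusion of per-cell values
#'
#' Personalized-propagation smoothing over the cell network: the fixed point
#' of `x = (1 - alpha) * P x + alpha * v`, with `P` the degree-normalized
#' weighted adjacency and `alpha` the restart probability. Solved by power
#' iteration to `tol` in the infinity norm. With row normalization a constant
#' input is a fixed point; with column normalization (`norm = "col"`, the
#' stochastic rearrangement) the total mass `sum(x) = sum(v)` is conserved at
#' the fixed point.
#'
#' @param net a `cell_network`.
#' @param values per-cell numeric vector, or a cells x m matrix of vectors
#'   diffused jointly.
#' @param alpha restart probability in `(0, 1)` (default 0.15).
#' @param norm `"row"` (default) or `"col"` normalization of the adjacency.
#' @param tol convergence tolerance (default 1e-6).
#' @param max_iter maximum power iterations (default 1000); non-convergence is
#'   an error reporting the residual.
#' @return Diffused vector (or matrix) of the same shape as `values`.
#' @export
diffuse_values <- function(net, values, alpha = 0.15, norm = c("row", "col"),
                           tol = 1e-6, max_iter = 1000) {
  stopifnot(inherits(net, "cell_network"))
  norm <- match.arg(norm)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  W <- net$weights
  n <- nrow(W)
  V <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  if (nrow(V) != n) stop("values length must equal the number of cells")

  if (norm == "row") {
    s <- Matrix::rowSums(W)
    P <- Diagonal(x = ifelse(s > 0, 1 / s, 0)) %*% W
  } else {
    s <- Matrix::colSums(W)
    P <- W %*% Diagonal(x = ifelse(s > 0, 1 / s, 0))
  }

  X <- V
  for (it in seq_len(max_iter)) {
    X_new <- as.matrix((1 - alpha) * (P %*% X) + alpha * V)
    res <- max(abs(X_new - X))
    X <- X_new
    if (res < tol) {
      return(if (is.matrix(values)) X else drop(X))
    }
  }
  stop(sprintf("diffusion did not converge in %d iterations (residual %.3g)",
               max_iter, res))
}

#' Marker-based cell annotation with permutation z-scores
#'
#' Scores each cell against each marker set by the signed average of
#' network-diffused marker expression: the expression matrix is passed through
#' [kernel_transform()] (so genes are comparably scaled), each marker gene's
#' vector is imputed by [diffuse_values()], and the per-cell score is the mean
#' over positive markers minus the mean over negative markers. Significance is
#' assessed against `n_perm` same-size random gene draws (diffusion is linear,
#' so each null draw diffuses its signed average directly), giving a per-cell
#' z-score for every label; the best label is the argmax.
#'
#' @param expr an `expr_matrix` of counts (or normalized expression).
#' @param net a `cell_network` over the same cells.
#' @param markers a list of [marker_set()] objects. Markers missing from the
#'   expression matrix are dropped with a warning; a set with no present
#'   markers is skipped with a warning.
#' @param n_perm permutations for the null (default 1000).
#' @param seed integer seed for the permutation draws.
#' @param alpha diffusion restart probability.
#' @return An object of class `cell_annotation` with per-cell `labels`,
#'   the cells x labels `zscores` matrix, and `confidence` (best z).
#' @export
annotate_cells <- function(expr, net, markers, n_perm = 1000, seed = 0,
                           alpha = 0.15) {
  expr <- as_expr_matrix(expr)
  stopifnot(inherits(net, "cell_network"))
  if (inherits(markers, "marker_set")) markers <- list(markers)
  n <- length(net$nodes)
  if (ncol(expr$values) != n) stop("expression and network cell counts differ")

  Z <- kernel_transform(expr)$values
  genes <- rownames(Z)

  keep <- list()
  for (ms in markers) {
    pos <- intersect(ms$positive, genes)
    neg <- intersect(ms$negative, genes)
    missing <- setdiff(c(ms$positive, ms$negative), genes)
    if (length(missing))
      warning("marker set '", ms$name, "': dropping missing genes: ",
              paste(missing, collapse = ", "))
    if (length(pos) + length(neg) == 0) {
      warning("marker set '", ms$name, "' has no genes in the data; skipped")
      next
    }
    keep[[ms$name]] <- list(pos = pos, neg = neg)
  }
  if (length(keep) == 0) stop("no usable marker sets")

  signed_avg <- function(pos, neg) {
    v <- if (length(pos)) colMeans(Z[pos, , drop = FALSE]) else numeric(n)
    if (length(neg)) v <- v - colMeans(Z[neg, , drop = FALSE])
    v
  }

  obs <- vapply(keep, function(ms) signed_avg(ms$pos, ms$neg), numeric(n))
  obs_diff <- diffuse_values(net, obs, alpha = alpha)

  zs <- matrix(NA_real_, n, length(keep),
               dimnames = list(net$nodes, names(keep)))
  for (li in seq_along(keep)) {
    npos <- length(keep[[li]]$pos); nneg <- length(keep[[li]]$neg)
    nulls <- with_seed(seed + li, {
      vapply(seq_len(n_perm), function(b) {
        gs <- sample(genes, npos + nneg)
        signed_avg(gs[seq_len(npos)], if (nneg) gs[(npos + 1):(npos + nneg)]
                   else character(0))
      }, numeric(n))
    })
    nulls <- diffuse_values(net, nulls, alpha = alpha)
    mu <- rowMeans(nulls)
    sdv <- apply(nulls, 1, sd)
    zs[, li] <- ifelse(sdv > 0, (obs_diff[, li] - mu) / sdv, 0)
  }

  best <- max.col(zs, ties.method = "first")
  labels <- colnames(zs)[best]
  names(labels) <- net$nodes
  structure(list(labels = labels, zscores = zs,
                 confidence = zs[cbind(seq_len(n), best)]),
            class = "cell_annotation")
}

#' Missing-label inference by significance-weighted label propagation
#'
#' Propagates a partial labeling over the network. Per iteration (synchronous
#' over cells), the evidence for label `l` at cell `i` is the total incident
#' edge weight to cells currently labeled `l`; it is compared against the
#' degree-weighted global frequency of `l` through a Chernoff-style upper
#' bound on the binomial tail,
#' `log p <= -s * KL(e/s || pi)` for `e/s > pi` (and `p = 1` otherwise),
#' which is monotone in the evidence. Unlabeled cells adopt the most
#' significant label; labeled cells switch only when the confidence ratio of
#' the challenger to the incumbent exceeds `ratio_threshold`. Labels never
#' leave the input label set.
#'
#' @param net a `cell_network`.
#' @param labels per-cell character/factor vector with `NA` for unlabeled
#'   cells; at least one labeled cell is required.
#' @param ratio_threshold confidence ratio required to switch an existing
#'   label (default 2).
#' @param max_iter maximum synchronous iterations (default 20); stops earlier
#'   at a fixed point.
#' @return A `cell_annotation` with inferred `labels`, the cells x labels
#'   confidence matrix (`-log10` bound) in `zscores`, and per-cell
#'   `confidence`.
#' @export
propagate_labels <- function(net, labels, ratio_threshold = 2.0,
                             max_iter = 20) {
  stopifnot(inherits(net, "cell_network"))
  n <- length(net$nodes)
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels length must equal the number of cells")
  if (all(is.na(labels))) stop("at least one labeled cell is required")
  lab_set <- sort(unique(labels[!is.na(labels)]))
  W <- net$weights
  deg <- Matrix::rowSums(W)

  cur <- labels
  conf_mat <- NULL
  for (it in seq_len(max_iter)) {
    Y <- sparseMatrix(i = which(!is.na(cur)),
                      j = match(cur[!is.na(cur)], lab_set),
                      x = 1, dims = c(n, length(lab_set)))
    E <- as.matrix(W %*% Y)                      # evidence per cell x label
    s <- as.numeric(W %*% (!is.na(cur)))         # incident weight to labeled
    degl <- vapply(lab_set, function(l) sum(deg[which(cur == l)]), numeric(1))
    pi_l <- degl / max(sum(degl), .Machine$double.eps)

    conf_mat <- matrix(0, n, length(lab_set),
                       dimnames = list(net$nodes, lab_set))
    for (li in seq_along(lab_set)) {
      q <- ifelse(s > 0, E[, li] / s, 0)
      p0 <- pi_l[li]
      ok <- q > p0 & s > 0 & p0 > 0 & p0 < 1
      klv <- rep(0, n)
      qq <- pmin(q[ok], 1 - 1e-12)
      klv[ok] <- qq * log(qq / p0) + (1 - qq) * log((1 - qq) / (1 - p0))
      conf_mat[, li] <- s * klv / log(10)        # -log10 bound
    }

    best <- max.col(conf_mat, ties.method = "first")
    best_conf <- conf_mat[cbind(seq_len(n), best)]
    nxt <- cur
    for (i in seq_len(n)) {
      if (best_conf[i] <= 0) next
      cand <- lab_set[best[i]]
      if (is.na(cur[i])) {
        nxt[i] <- cand
      } else if (cand != cur[i]) {
        inc <- conf_mat[i, match(cur[i], lab_set)]
        if (best_conf[i] >= ratio_threshold * max(inc, .Machine$double.eps))
          nxt[i] <- cand
      }
    }
    changed <- !identical(nxt, cur)
    cur <- nxt
    if (!changed) break
  }

  names(cur) <- net$nodes
  best <- max.col(conf_mat, ties.method = "first")
  structure(list(labels = cur, zscores = conf_mat,
                 confidence = conf_mat[cbind(seq_len(n),
                                             ifelse(is.na(cur), best,
                                                    match(cur, lab_set)))]),
            class = "cell_annotation")
}

#' Per-cell footprint of one multiresolution state
#'
#' The degree to which one state pattern contributes to each cell's
#' transcriptome: the state's row of `H_mr`, optionally diffusion-smoothed
#' over the network for visualization.
#'
#' @param states a `multires_states`.
#' @param which state index (row of `H_mr`).
#' @param net optional `cell_network`; if given, the footprint is smoothed
#'   with [diffuse_values()].
#' @param alpha diffusion restart probability when smoothing.
#' @return Per-cell numeric vector.
#' @export
footprint <- function(states, which, net = NULL, alpha = 0.15) {
  stopifnot(inherits(states, "multires_states"))
  if (length(which) != 1 || which < 1 || which > nrow(states$H_mr))
    stop("state index out of range")
  v <- states$H_mr[which, ]
  if (!is.null(net)) v <- diffuse_values(net, v, alpha = alpha)
  v
}

#' Permutation enrichment of cell measurements in state encodings
#'
#' Assesses the overrepresentation of per-cell measurements in each state's
#' encoding: the observed statistic is `H_mr %*% values`, the null permutes
#' the cell order `n_perm` times, and each (state, feature) pair gets a
#' z-score. Categorical input is one-hot encoded internally. A constant
#' feature is permutation-invariant and scores 0.
#'
#' @param states a `multires_states`.
#' @param cell_values per-cell numeric vector, cells x features numeric
#'   matrix, or a factor/character vector (one-hot encoded).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return states x features z-score matrix.
#' @export
state_enrichment <- function(states, cell_values, n_perm = 1000, seed = 0) {
  stopifnot(inherits(states, "multires_states"))
  H <- states$H_mr
  n <- ncol(H)
  if (is.factor(cell_values) || is.character(cell_values)) {
    f <- factor(cell_values)
    V <- sapply(levels(f), function(l) as.numeric(f == l))
  } else if (is.matrix(cell_values)) {
    V <- cell_values
  } else {
    V <- matrix(as.numeric(cell_values), ncol = 1)
  }
  if (nrow(V) != n) stop("cell_values length must equal the number of cells")

  obs <- H %*% V
  m1 <- 0; m2 <- 0
  lo <- NULL; hi <- NULL
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- as.matrix(H %*% V[sample(n), , drop = FALSE])
      m1 <- m1 + perm
      m2 <- m2 + perm^2
      lo <- if (is.null(lo)) perm else pmin(lo, perm)
      hi <- if (is.null(hi)) perm else pmax(hi, perm)
    }
  })
  mu <- m1 / n_perm
  sdv <- sqrt(pmax(m2 / n_perm - mu^2, 0) * n_perm / max(n_perm - 1, 1))
  # permutation-invariant statistics (e.g. constant features) give a null
  # with zero spread; detect via the exact range to avoid cancellation noise
  degenerate <- (hi - lo) <= 1e-10 * pmax(abs(mu), 1)
  z <- ifelse(!degenerate & sdv > 0, (obs - mu) / sdv, 0)
  dimnames(z) <- list(rownames(H), colnames(V))
  as.matrix(z)
}

#' Graph clustering of the cell network
#'
#' Leiden community detection (modularity objective) on the weighted cell
#' network; a convenience for cluster-style analyses of the network.
#'
#' @param net a `cell_network`.
#' @param resolution Leiden resolution (default 1); as it approaches 0 every
#'   connected component collapses to one cluster.
#' @param seed integer seed.
#' @return Integer vector of per-cell cluster labels.
#' @export
cluster_network <- function(net, resolution = 1.0, seed = 0) {
  stopifnot(inherits(net, "cell_network"))
  g <- network_graph(net)
  member <- with_seed(seed, {
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = resolution,
      weights = igraph::E(g)$weight, n_iterations = 10))
  })
  out <- as.integer(member)
  names(out) <- net$nodes
  out
}
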