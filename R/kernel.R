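#' Expression kernel transform
#'
#' Transforms a raw (or library-normalized) count matrix into the feature
#' space whose inner products define the expression kernel used by the
#' archetypal decomposition. The chain is: median-library-size normalization
#' per cell, `log1p`, then per-gene z-scoring with winsorization of the z
#' values at `+/- z_limit`. Centering and scaling down-weight ubiquitously
#' expressed genes and boost genes expressed in a cell-specific manner, so no
#' highly-variable-gene preselection is performed. Genes with zero variance
#' (including all-zero genes) are retained but mapped to zero weight.
#'
#' @param expr an [expression_matrix()] (or bare matrix) of non-negative
#'   counts or library-normalized values; no `NaN` allowed. Cells whose column
#'   is entirely zero are rejected with a diagnostic naming them.
#' @param z_limit winsorization limit for per-gene z values (default 10).
#' @return An `expr_matrix` of the same shape holding the transformed (dense)
#'   matrix; the applied chain is recorded in the `transform` attribute so
#'   downstream results can pin it.
#' @export
kernel_transform <- function(expr, z_limit = 10) {
  expr <- as_expr_matrix(expr)
  X <- expr$values
  if (anyNA(X)) stop("expression matrix contains NA/NaN")
  if (min(X) < 0) stop("expression matrix contains negative entries")
  libs <- Matrix::colSums(X)
  if (any(libs == 0))
    stop("all-zero cell columns: ",
         paste(expr$cell_names[libs == 0], collapse = ", "))

  med <- stats::median(libs)
  X <- X %*% Diagonal(x = med / libs)      # library-size normalization
  X <- as.matrix(X)
  X <- log1p(X)

  rm_ <- rowMeans(X)
  rsd <- sqrt(rowSums((X - rm_)^2) / max(1, ncol(X) - 1))
  Z <- (X - rm_) / ifelse(rsd > 0, rsd, 1)
  Z[rsd == 0, ] <- 0                       # constant genes carry zero weight
  Z <- pmin(pmax(Z, -z_limit), z_limit)

  out <- expression_matrix(Z, expr$gene_names, expr$cell_names)
  attr(out, "transform") <- list(chain = c("median_library_normalize",
                                           "log1p", "gene_zscore", "winsorize"),
                                 z_limit = z_limit)
  out
}

#' Rank-D reduction of the kernel feature matrix
#'
#' Computes a rank-`dim` factorization of the transformed matrix `Z` with a
#' seeded randomized SVD (Gaussian sketch, QR re-orthonormalized power
#' iterations), so that the Gram matrix of the returned reduced profile
#' approximates the expression kernel `K = t(Z) %*% Z` at rank D. The result
#' is bitwise reproducible for a fixed seed.
#'
#' @param Z transformed expression matrix (from [kernel_transform()]), an
#'   `expr_matrix` or bare matrix; sparse input is supported.
#' @param dim reduced rank D; must satisfy `2 <= dim < min(dim(Z))`.
#' @param seed integer seed driving the random sketch.
#' @param oversampling extra sketch columns beyond D (default 10).
#' @param power_iter subspace power iterations (default 5); each is
#'   re-orthonormalized for numerical stability on sparse inputs.
#' @return A [reduced_profile()] with `S_r` (D x cells), the top D singular
#'   values, and the gene loadings used to map patterns back to gene space.
#' @export
reduce_profile <- function(Z, dim = 50, seed = 0, oversampling = 10,
                           power_iter = 5) {
  em <- as_expr_matrix(Z)
  X <- em$values
  g <- nrow(X); n <- ncol(X)
  if (dim < 2 || dim >= min(g, n))
    stop("reduced rank must satisfy 2 <= dim < min(genes, cells)")
  l <- min(dim + oversampling, min(g, n))

  with_seed(seed, {
    Omega <- matrix(rnorm(n * l), n, l)
    Q <- qr.Q(qr(as.matrix(X %*% Omega)))
    for (i in seq_len(power_iter)) {
      Q <- qr.Q(qr(as.matrix(crossprod(X, Q))))
      Q <- qr.Q(qr(as.matrix(X %*% Q)))
    }
    B <- as.matrix(crossprod(Q, X))        # l x n
    sv <- svd(B)
    U <- Q %*% sv$u[, seq_len(dim), drop = FALSE]
    d <- sv$d[seq_len(dim)]
    V <- sv$v[, seq_len(dim), drop = FALSE]
    # deterministic sign convention: dominant loading of each component > 0
    for (j in seq_len(dim)) {
      s <- sign(U[which.max(abs(U[, j])), j])
      if (s < 0) { U[, j] <- -U[, j]; V[, j] <- -V[, j] }
    }
    S_r <- t(V * rep(d, each = nrow(V)))   # D x n, equals diag(d) %*% t(V)
    rownames(U) <- em$gene_names
    reduced_profile(S_r, d, U, em$cell_names,
                    transform = attr(Z, "transform"))
  })
}

#' Adopt an externally reduced (e.g. batch-corrected) matrix
#'
#' Hook for workflows that correct the reduced representation with an
#' external tool: wraps a precomputed D x cells matrix as a
#' [reduced_profile()] so it can be consumed by the decompositions in place
#' of [reduce_profile()] output. No correction is performed here.
#'
#' @param S_r D x cells matrix.
#' @param gene_loadings optional genes x D back-projection matrix; identity
#'   if omitted.
#' @param cell_names optional cell names.
#' @param singular_values optional; column-energy estimates are used if absent.
#' @return A [reduced_profile()].
#' @export
as_reduced_profile <- function(S_r, gene_loadings = NULL, cell_names = NULL,
                               singular_values = NULL) {
  S_r <- as.matrix(S_r)
  D <- nrow(S_r)
  if (is.null(singular_values)) {
    singular_values <- sort(sqrt(pmax(rowSums(S_r^2), 0)), decreasing = TRUE)
  }
  reduced_profile(S_r, singular_values,
                  gene_loadings %||% diag(D),
                  cell_names %||% colnames(S_r) %||%
                    paste0("cell_", seq_len(ncol(S_r))))
}
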