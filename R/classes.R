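#' Expression matrix container
#'
#' Lightweight container for a genes-by-cells expression matrix (dense or
#' sparse) with gene and cell names. This is the entry point of the pipeline;
#' raw counts and transformed matrices share the same container.
#'
#' @param values genes x cells numeric matrix (`matrix` or a `Matrix` sparse
#'   class). Rows are genes, columns are cells.
#' @param gene_names,cell_names character vectors naming rows/columns. If
#'   `NULL`, taken from `dimnames(values)` or generated.
#' @param counts logical; declare the matrix as raw counts, in which case
#'   negative entries are rejected.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `gene_names`, `cell_names`.
#' @export
expression_matrix <- function(values, gene_names = NULL, cell_names = NULL,
                              counts = FALSE) {
  if (!(is.matrix(values) || is(values, "Matrix")))
    stop("`values` must be a matrix or Matrix")
  gene_names <- gene_names %||% rownames(values) %||%
    paste0("gene_", seq_len(nrow(values)))
  cell_names <- cell_names %||% colnames(values) %||%
    paste0("cell_", seq_len(ncol(values)))
  if (length(gene_names) != nrow(values))
    stop("gene_names length must equal the number of rows")
  if (length(cell_names) != ncol(values))
    stop("cell_names length must equal the number of columns")
  if (counts && min(values) < 0)
    stop("counts matrix contains negative entries")
  dimnames(values) <- list(gene_names, cell_names)
  structure(list(values = values, gene_names = gene_names,
                 cell_names = cell_names),
            class = "expr_matrix")
}

#' @method print expr_matrix
#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells (%s)\n",
              nrow(x$values), ncol(x$values), class(x$values)[1]))
  invisible(x)
}

as_expr_matrix <- function(x, ...) {
  if (inherits(x, "expr_matrix")) x else expression_matrix(x, ...)
}

#' Reduced profile container
#'
#' Rank-D representation of the transformed expression matrix: `S_r` is the
#' D x cells matrix whose Gram matrix approximates the expression kernel, and
#' `gene_loadings` maps reduced-space patterns back to gene space.
#'
#' @param S_r D x cells numeric matrix.
#' @param singular_values length-D non-increasing, non-negative vector.
#' @param gene_loadings genes x D matrix (may be an identity for fixtures
#'   built directly in reduced space).
#' @param cell_names character vector of cell identifiers.
#' @param transform optional record of the transform chain that produced the
#'   underlying matrix.
#' @return An object of class `reduced_profile`.
#' @export
reduced_profile <- function(S_r, singular_values, gene_loadings, cell_names,
                            transform = NULL) {
  D <- nrow(S_r)
  if (D < 2) stop("reduced rank D must be at least 2")
  if (length(singular_values) != D)
    stop("singular_values must have length D")
  if (any(diff(singular_values) > 1e-8) || any(singular_values < -1e-12))
    stop("singular_values must be non-increasing and non-negative")
  if (ncol(gene_loadings) != D) stop("gene_loadings must have D columns")
  if (length(cell_names) != ncol(S_r))
    stop("cell_names length must equal the number of cells")
  colnames(S_r) <- cell_names
  structure(list(S_r = S_r, D = D, singular_values = singular_values,
                 gene_loadings = gene_loadings, cell_names = cell_names,
                 transform = transform),
            class = "reduced_profile")
}

#' @method print reduced_profile
#' @export
print.reduced_profile <- function(x, ...) {
  cat(sprintf("<reduced_profile> D = %d, %d cells, %d genes\n",
              x$D, ncol(x$S_r), nrow(x$gene_loadings)))
  invisible(x)
}

#' @method print archetype_fit
#' @export
print.archetype_fit <- function(x, ...) {
  cat(sprintf("<archetype_fit> k = %d, %d cells, objective %.6g after %d iterations\n",
              x$k, ncol(x$H), x$objective_trace[length(x$objective_trace)],
              length(x$objective_trace)))
  invisible(x)
}

#' @method print multilevel_fit
#' @export
print.multilevel_fit <- function(x, ...) {
  cat(sprintf("<multilevel_fit> k = %d..%d, T = %d patterns, %d cells\n",
              x$k_min, x$k_max, x$T, ncol(x$H_star)))
  invisible(x)
}

#' @method print cell_network
#' @export
print.cell_network <- function(x, ...) {
  ne <- length(x$weights@x) / 2
  cat(sprintf("<cell_network> %d cells, %d undirected edges, kappa = %g\n",
              length(x$nodes), round(ne), x$kappa))
  invisible(x)
}

#' @method print multires_states
#' @export
print.multires_states <- function(x, ...) {
  cat(sprintf("<multires_states> %d representative states (from %d multilevel patterns)\n",
              nrow(x$selected), sum(x$dominance)))
  invisible(x)
}

#' @method print state_embedding
#' @export
print.state_embedding <- function(x, ...) {
  cat(sprintf("<state_embedding> %d cells in %dD, compactness %d\n",
              nrow(x$coords), ncol(x$coords), x$compactness))
  invisible(x)
}

#' @method as.data.frame state_embedding
#' @export
as.data.frame.state_embedding <- function(x, ...) {
  df <- as.data.frame(x$coords)
  names(df) <- paste0("dim", seq_len(ncol(df)))
  df$cell <- rownames(x$coords) %||% as.character(seq_len(nrow(df)))
  df
}

#' @method print cell_annotation
#' @export
print.cell_annotation <- function(x, ...) {
  tab <- table(x$labels, useNA = "ifany")
  cat(sprintf("<cell_annotation> %d cells, %d labels\n",
              length(x$labels), ncol(x$zscores)))
  print(tab)
  invisible(x)
}

#' @method as.data.frame cell_annotation
#' @export
as.data.frame.cell_annotation <- function(x, ...) {
  data.frame(cell = names(x$labels) %||% as.character(seq_along(x$labels)),
             label = x$labels, confidence = x$confidence,
             row.names = NULL)
}

#' Marker gene set
#'
#' A named set of positive and (optionally) negative marker genes used for
#' network-based cell annotation.
#'
#' @param name label name.
#' @param positive,negative character vectors of gene names. The two sets must
#'   be disjoint and at least one marker must be given.
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(name, positive = character(), negative = character()) {
  positive <- unique(as.character(positive))
  negative <- unique(as.character(negative))
  if (length(intersect(positive, negative)) > 0)
    stop("marker set '", name, "': genes listed as both positive and negative: ",
         paste(intersect(positive, negative), collapse = ", "))
  if (length(positive) + length(negative) == 0)
    stop("marker set '", name, "' has no markers")
  structure(list(name = name, positive = positive, negative = negative),
            class = "marker_set")
}
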