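#' Influential cells of an archetype
#'
#' The sparse support of one archetype: indices of cells whose coefficient in
#' the corresponding column of `C` exceeds the nonzero threshold. The size of
#' this set is empirically independent of data set size, which is what makes
#' overlap between supports a meaningful pattern-similarity signal.
#'
#' @param c_col one column of a `C` matrix.
#' @param threshold nonzero threshold (default 1e-5).
#' @return Integer vector of influential cell indices.
#' @export
influential_cells <- function(c_col, threshold = 1e-5) {
  which(as.numeric(c_col) > threshold)
}

#' Overlap significance between two influential-cell sets
#'
#' Hypergeometric upper-tail probability of observing at least the given
#' overlap between two cell sets drawn from `n_cells` cells; symmetric in its
#' arguments.
#'
#' @param set_a,set_b integer index sets (subsets of `1:n_cells`).
#' @param n_cells universe size.
#' @return Upper-tail p-value `P(X >= |intersection|)`.
#' @export
overlap_significance <- function(set_a, set_b, n_cells) {
  set_a <- unique(as.integer(set_a)); set_b <- unique(as.integer(set_b))
  if (length(set_a) == 0 || length(set_b) == 0) {
    warning("empty influential-cell set; returning p = 1")
    return(1.0)
  }
  if (any(c(set_a, set_b) < 1) || any(c(set_a, set_b) > n_cells))
    stop("set indices outside 1..n_cells")
  ov <- length(intersect(set_a, set_b))
  phyper(ov - 1, length(set_b), n_cells - length(set_b), length(set_a),
         lower.tail = FALSE)
}

#' Prune the multilevel pattern set to multiresolution states
#'
#' Collapses the `T` multilevel archetypes into a nonredundant set of
#' cell-state patterns. A pattern graph is built with one node per archetype
#' and an edge wherever the hypergeometric overlap of influential-cell sets is
#' significant (`p < sig_threshold`), weighted by `-log10(p)` capped at 300.
#' Leiden clustering of this graph defines equivalence classes; each class is
#' represented by its member discovered at the lowest resolution (smallest
#' `k`, ties broken by the within-level index), on the grounds that the
#' low-resolution pattern already carries the shared information. The
#' representatives' columns/rows of `W_star`, `H_star`, `C_star` form the
#' multiresolution decomposition; class size is reported as dominance.
#'
#' @param ml a `multilevel_fit`.
#' @param sig_threshold overlap p-value cutoff for pattern-graph edges
#'   (default 0.01).
#' @param resolution Leiden resolution parameter (default 2). The pattern
#'   graph carries many small equivalence cliques (one per recurring state)
#'   bridged by coarse low-resolution patterns; at resolution 1 weighted
#'   modularity hits its resolution limit and absorbs fine cliques into
#'   coarse-anchored communities, so a moderately higher resolution is needed
#'   to keep distinct states in distinct classes.
#' @param seed seed for the Leiden refinement.
#' @param threshold nonzero threshold defining influential cells.
#' @return An object of class `multires_states` with `selected` (data frame of
#'   class, `k`, `index`, concatenated column), `W_mr`, `H_mr`, `C_mr`,
#'   `class_members` and `dominance`.
#' @export
prune_multilevel <- function(ml, sig_threshold = 0.01, resolution = 2.0,
                             seed = 0, threshold = 1e-5) {
  stopifnot(inherits(ml, "multilevel_fit"))
  Tn <- ml$T
  n <- nrow(ml$C_star)

  M <- ml$C_star > threshold
  sizes <- colSums(M)
  OV <- crossprod(M * 1)                  # T x T overlap counts

  ut <- which(upper.tri(OV) & OV > 0, arr.ind = TRUE)
  if (nrow(ut) > 0) {
    sa <- sizes[ut[, 1]]; sb <- sizes[ut[, 2]]
    ov <- OV[ut]
    p <- phyper(ov - 1, sb, n - sb, sa, lower.tail = FALSE)
    keep <- p < sig_threshold
    ut <- ut[keep, , drop = FALSE]
    w <- pmin(-log10(pmax(p[keep], 1e-300)), 300)
  } else {
    w <- numeric(0)
  }

  if (nrow(ut) == 0) {
    warning("no significant pattern overlaps; every pattern is its own class")
    member <- seq_len(Tn)
  } else {
    g <- igraph::make_empty_graph(n = Tn, directed = FALSE)
    g <- igraph::add_edges(g, t(ut))
    igraph::E(g)$weight <- w
    member <- with_seed(seed, {
      igraph::membership(igraph::cluster_leiden(
        g, objective_function = "modularity",
        resolution = resolution, weights = igraph::E(g)$weight,
        n_iterations = 10))
    })
    member <- as.integer(member)
  }

  classes <- sort(unique(member))
  sel <- lapply(classes, function(cl) {
    members <- which(member == cl)
    o <- order(ml$level_of$k[members], ml$level_of$index[members])
    rep_col <- members[o[1]]
    list(members = members, rep = rep_col)
  })
  rep_cols <- vapply(sel, `[[`, integer(1), "rep")
  ord <- order(ml$level_of$k[rep_cols], ml$level_of$index[rep_cols])
  sel <- sel[ord]
  rep_cols <- rep_cols[ord]

  selected <- data.frame(class = seq_along(rep_cols),
                         k = ml$level_of$k[rep_cols],
                         index = ml$level_of$index[rep_cols],
                         column = rep_cols)
  structure(list(selected = selected,
                 W_mr = ml$W_star[, rep_cols, drop = FALSE],
                 H_mr = ml$H_star[rep_cols, , drop = FALSE],
                 C_mr = ml$C_star[, rep_cols, drop = FALSE],
                 class_members = lapply(sel, `[[`, "members"),
                 dominance = vapply(sel, function(s) length(s$members),
                                    integer(1)),
                 n_levels = length(ml$levels)),
            class = "multires_states")
}
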