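#' Synthetic benchmark configuration
#'
#' Configuration of the ground-truth benchmark generator: a fixed number of
#' identity programs (each defining one discrete cell type) plus activity
#' programs shared as a gradient across several types, realized as
#' negative-binomial counts at one of three noise levels.
#'
#' @param n_identity_programs number of identity programs / cell types
#'   (default 13).
#' @param n_activity_programs number of shared activity programs (default 1).
#' @param cells_per_type cells per identity type (default 50).
#' @param n_genes number of genes (default 560).
#' @param noise_level `"low"`, `"mid"` or `"high"`; controls the
#'   negative-binomial dispersion (0.1, 0.5, 1.5 respectively).
#' @param activity_gradient logical; if `TRUE` (default) activity loadings are
#'   uniform in `[0, 1]` (a gradient), otherwise constant 1 for affected cells.
#' @param seed integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_identity_programs = 13,
                             n_activity_programs = 1,
                             cells_per_type = 50,
                             n_genes = 560,
                             noise_level = c("low", "mid", "high"),
                             activity_gradient = TRUE,
                             seed = 1) {
  noise_level <- match.arg(noise_level)
  stopifnot(n_identity_programs >= 1, n_activity_programs >= 0,
            cells_per_type >= 1, n_genes >= 1)
  structure(list(n_identity_programs = as.integer(n_identity_programs),
                 n_activity_programs = as.integer(n_activity_programs),
                 cells_per_type = as.integer(cells_per_type),
                 n_genes = as.integer(n_genes),
                 noise_level = noise_level,
                 activity_gradient = isTRUE(activity_gradient),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

noise_dispersion <- c(low = 0.1, mid = 0.5, high = 1.5)

#' Generate a ground-truth benchmark count matrix
#'
#' Draws per-program gene signatures with disjoint top-marker blocks, builds
#' per-cell rates as identity signature plus activity-loading-weighted
#' activity signature on top of a lognormal baseline, and samples counts from
#' a negative binomial whose dispersion is set by the configured noise level.
#' Each activity program affects a contiguous half of the identity types, with
#' a uniform gradient of loadings mimicking an activation state radiating
#' through otherwise distinct types. Fully reproducible for a fixed seed.
#'
#' @param config a [synthetic_config()].
#' @return A list with `expr` (an [expression_matrix()] of counts, sparse) and
#'   `truth`: `cell_type` (per-cell integer), `program_loadings`
#'   (programs x cells; identity rows one-hot, activity rows in `[0, 1]`),
#'   `program_signatures` (genes x programs) and `program_type`.
#' @export
generate_benchmark <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  P <- config$n_identity_programs + config$n_activity_programs
  G <- config$n_genes
  block <- floor(0.5 * G / P)
  if (block < 5)
    stop("config error: fewer genes than programs allow (need >= ",
         10 * P, " genes for ", P, " programs)")
  n <- config$n_identity_programs * config$cells_per_type
  disp <- noise_dispersion[[config$noise_level]]

  with_seed(config$seed, {
    base <- rlnorm(G, meanlog = log(0.2), sdlog = 0.5)
    sig <- matrix(0, G, P)
    for (p in seq_len(P)) {
      rows <- ((p - 1) * block + 1):(p * block)
      sig[rows, p] <- runif(block, 2, 6)
    }

    cell_type <- rep(seq_len(config$n_identity_programs),
                     each = config$cells_per_type)
    loadings <- matrix(0, P, n)
    loadings[cbind(cell_type, seq_len(n))] <- 1
    if (config$n_activity_programs > 0) {
      n_active_types <- ceiling(config$n_identity_programs / 2)
      for (ap in seq_len(config$n_activity_programs)) {
        row <- config$n_identity_programs + ap
        affected <- which(cell_type <= n_active_types)
        loadings[row, affected] <-
          if (config$activity_gradient) runif(length(affected)) else 1
      }
    }

    mu <- base + sig %*% loadings          # genes x cells rates
    depth <- rlnorm(n, 0, 0.15)
    mu <- sweep(mu, 2, depth, "*")
    counts <- matrix(rnbinom(G * n, mu = as.vector(mu), size = 1 / disp), G, n)
    expr <- expression_matrix(Matrix(counts, sparse = TRUE),
                              paste0("gene_", seq_len(G)),
                              paste0("cell_", seq_len(n)),
                              counts = TRUE)
    rownames(loadings) <- colnames(sig) <-
      c(paste0("identity_", seq_len(config$n_identity_programs)),
        if (config$n_activity_programs > 0)
          paste0("activity_", seq_len(config$n_activity_programs)))
    rownames(sig) <- expr$gene_names
    colnames(loadings) <- expr$cell_names
    list(expr = expr,
         truth = list(cell_type = cell_type,
                      program_loadings = loadings,
                      program_signatures = sig,
                      program_type = rep(c("identity", "activity"),
                                         c(config$n_identity_programs,
                                           config$n_activity_programs))))
  })
}

#' Convex-hull geometry fixture in reduced space
#'
#' Plants `k` random vertices in `R^D` and draws the remaining cells as
#' Dirichlet convex combinations of them; the vertices themselves are included
#' verbatim as the first `k` cells. Supports exact-recovery oracles for the
#' archetypal decomposition.
#'
#' @param D ambient dimension (>= 2).
#' @param k number of planted vertices, `1 <= k <= n_cells`.
#' @param n_cells total cells.
#' @param seed integer seed.
#' @param concentration Dirichlet concentration for the mixing weights
#'   (default 0.3; values < 1 keep most cells near the hull boundary).
#' @return A [reduced_profile()] whose `S_r` holds the cells, with the planted
#'   vertex indices in attribute `"planted"`.
#' @export
hull_fixture <- function(D, k, n_cells, seed = 1, concentration = 0.3) {
  if (k > n_cells) stop("k cannot exceed n_cells")
  with_seed(seed, {
    V <- matrix(rnorm(D * k, sd = 3), D, k)
    X <- matrix(0, D, n_cells)
    X[, seq_len(k)] <- V
    if (n_cells > k) {
      Wm <- matrix(rgamma((n_cells - k) * k, shape = concentration), k)
      Wm <- sweep(Wm, 2, colSums(Wm), "/")
      X[, (k + 1):n_cells] <- V %*% Wm
    }
    sv <- svd(X, nu = 0, nv = 0)$d
    sv <- c(sv, rep(0, max(0, D - length(sv))))[seq_len(D)]
    out <- reduced_profile(X, sv, diag(D),
                           paste0("cell_", seq_len(n_cells)))
    attr(out, "planted") <- seq_len(k)
    out
  })
}

# Min-cost assignment (Hungarian algorithm, shortest augmenting paths with
# potentials). cost: n x m with n >= m; returns for each column the assigned
# row index.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n >= m)
  # column-major loop over columns as "items", rows as "slots"
  u <- numeric(m + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)   # p[j+1]: column matched to row j
  for (i in seq_len(m)) {
    p[1] <- i; j0 <- 0
    minv <- rep(Inf, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[j, i0] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) { u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
                           v[j + 1] <- v[j + 1] - delta }
        else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign_col <- integer(m)
  for (j in seq_len(n)) if (p[j + 1] > 0) assign_col[p[j + 1]] <- j
  assign_col
}

# Welch's unequal-variance t statistic with Welch-Satterthwaite degrees of
# freedom, one-sided (mean(x) > mean(y)); returns -log10 p, capped.
welch_score <- function(x, y, cap = 300) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) return(0)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 <= 0) return(if (m1 > m2) cap else 0)
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  logp <- pt(t, df, lower.tail = FALSE, log.p = TRUE) / log(10)
  min(-logp, cap)
}

#' Match recovered states against ground-truth programs
#'
#' Scores every (state, program) pair by the capture rate: the `-log10` p of
#' Welch's one-sided t test comparing the state's `H_mr` encoding between
#' program-positive and program-negative cells. Programs are assigned to
#' states one-to-one by an optimal assignment (Hungarian algorithm) that first
#' maximizes the number of programs with a significant capture score and then
#' the total capture; a program counts as matched when its assigned score
#' reaches `score_threshold`. When a
#' gene-space mapping is available, purity is reported as the Pearson
#' correlation between the matched state's gene-space profile and the true
#' program signature.
#'
#' @param states a `multires_states` (or any object with an `H_mr` matrix).
#' @param truth ground truth list from [generate_benchmark()].
#' @param gene_loadings optional genes x D back-projection (from the
#'   [reduce_profile()] output) used to map `W_mr` to gene space for purity;
#'   if `NULL` and `W_mr` is already in gene space it is used directly.
#' @param score_threshold capture-rate threshold declaring a program matched
#'   (default 3, i.e. p <= 1e-3).
#' @return A data frame (class `recovery_report`) with one row per program:
#'   `program`, `type`, matched `state`, `score`, `purity`, `matched`; the
#'   number of matched programs is in attribute `"n_matched"`.
#' @export
evaluate_recovery <- function(states, truth, gene_loadings = NULL,
                              score_threshold = 3) {
  H <- states$H_mr
  L <- truth$program_loadings
  P <- nrow(L); m <- nrow(H); n <- ncol(H)
  if (ncol(L) != n) stop("states and truth disagree on the number of cells")

  score <- matrix(0, m, P)
  for (p in seq_len(P)) {
    pos <- L[p, ] > 0
    for (s in seq_len(m)) score[s, p] <- welch_score(H[s, pos], H[s, !pos])
  }

  assigned_state <- rep(NA_integer_, P)
  assigned_score <- rep(0, P)
  if (m >= P) {
    # optimal one-to-one assignment: first maximize the number of programs
    # with a significant capture score, then the total capture
    benefit <- score + 1e6 * (score >= score_threshold)
    sol <- solve_assignment(max(benefit) - benefit)
    for (p in seq_len(P)) {
      assigned_state[p] <- sol[p]
      assigned_score[p] <- score[sol[p], p]
    }
  } else {
    # fewer states than programs: greedy on the best remaining pair
    Sm <- score
    for (step in seq_len(m)) {
      top <- which(Sm == max(Sm), arr.ind = TRUE)[1, ]
      if (Sm[top[1], top[2]] <= 0) break
      assigned_state[top[2]] <- top[1]
      assigned_score[top[2]] <- Sm[top[1], top[2]]
      Sm[top[1], ] <- -Inf
      Sm[, top[2]] <- -Inf
    }
  }

  purity <- rep(NA_real_, P)
  Wg <- NULL
  if (!is.null(states$W_mr)) {
    if (!is.null(gene_loadings)) {
      Wg <- gene_loadings %*% states$W_mr
    } else if (nrow(states$W_mr) == nrow(truth$program_signatures)) {
      Wg <- states$W_mr
    }
  }
  if (!is.null(Wg)) {
    for (p in seq_len(P)) {
      if (!is.na(assigned_state[p]))
        purity[p] <- suppressWarnings(
          cor(Wg[, assigned_state[p]], truth$program_signatures[, p]))
    }
  }

  matched <- !is.na(assigned_state) & assigned_score >= score_threshold
  out <- data.frame(program = rownames(L) %||% paste0("program_", seq_len(P)),
                    type = truth$program_type %||% rep(NA_character_, P),
                    state = assigned_state,
                    score = assigned_score,
                    purity = purity,
                    matched = matched)
  attr(out, "n_matched") <- sum(matched)
  attr(out, "score_matrix") <- score
  class(out) <- c("recovery_report", "data.frame")
  out
}
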