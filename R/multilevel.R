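#' Multilevel archetypal decomposition
#'
#' Runs the single-level decomposition independently at every resolution
#' `k = k_min, ..., k_max` and concatenates the per-level factors into the
#' multilevel matrices `C_star` (cells x T), `H_star` (T x cells) and `W_star`
#' (D x T), with `T = sum(k_min:k_max)`. Levels are computed independently, so
#' the result does not depend on evaluation order and individual levels can be
#' recomputed in isolation.
#'
#' @param S_r a [reduced_profile()] (or bare D x cells matrix).
#' @param k_min,k_max resolution range (defaults 2 and 30; convergence of the
#'   saturation curve is typically reached below k = 30).
#' @inheritParams aa_refine
#' @return An object of class `multilevel_fit` with the per-level fits in
#'   `levels`, the concatenated `C_star`, `H_star`, `W_star`, a `level_of`
#'   data frame mapping concatenated columns to `(k, index)`, and `T`.
#' @export
run_multilevel <- function(S_r, k_min = 2, k_max = 30, max_iter = 100,
                           tol = 1e-6) {
  if (k_min < 2 || k_min > k_max) stop("need 2 <= k_min <= k_max")
  ks <- k_min:k_max
  levels <- lapply(ks, function(k) run_archetypes(S_r, k, max_iter, tol))
  names(levels) <- paste0("k", ks)

  C_star <- do.call(cbind, lapply(levels, `[[`, "C"))
  H_star <- do.call(rbind, lapply(levels, `[[`, "H"))
  W_star <- do.call(cbind, lapply(levels, `[[`, "W"))
  level_of <- data.frame(k = rep(ks, ks),
                         index = unlist(lapply(ks, seq_len), use.names = FALSE))
  Tn <- sum(ks)
  stopifnot(nrow(level_of) == Tn, ncol(C_star) == Tn)
  pat <- paste0("k", level_of$k, "_a", level_of$index)
  colnames(C_star) <- pat
  rownames(H_star) <- pat
  colnames(W_star) <- pat

  structure(list(levels = levels, C_star = C_star, H_star = H_star,
                 W_star = W_star, level_of = level_of, T = Tn,
                 k_min = k_min, k_max = k_max),
            class = "multilevel_fit")
}

#' Saturation curve of nontrivial archetype columns
#'
#' For each resolution level, counts the columns of that level's `C` matrix
#' with more than one entry above the nonzero threshold. Surplus archetypes
#' beyond the number of distinct states in the data stay at their single-cell
#' initialization, so the count plateaus once the resolution exceeds the
#' number of states; the plateau locates an effective `k_max`.
#'
#' @param ml a `multilevel_fit`.
#' @param threshold coefficient magnitude treated as nonzero (default 1e-5).
#' @return A data frame with columns `k` and `nontrivial`.
#' @export
saturation_curve <- function(ml, threshold = 1e-5) {
  stopifnot(inherits(ml, "multilevel_fit"))
  counts <- vapply(ml$levels, function(lv) {
    sum(colSums(lv$C > threshold) > 1L)
  }, integer(1))
  data.frame(k = ml$k_min:ml$k_max, nontrivial = unname(counts))
}
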