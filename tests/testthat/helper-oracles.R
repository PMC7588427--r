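# Independent oracles used across test files. These deliberately re-derive
# results by direct, unoptimized computation so they share no code path with
# the implementation under test.

# literal line-by-line transcription of the k*-NN neighbor-count procedure
kstar_oracle <- function(beta) {
  N <- length(beta)
  if (N < 2) return(max(N - 1L, 0L))
  Sb <- 0; Sb2 <- 0
  lam <- beta[1] + 1
  n_opt <- N - 1L
  for (n in 1:(N - 1)) {
    if (lam <= beta[n]) { n_opt <- n; break }
    Sb <- Sb + beta[n]
    Sb2 <- Sb2 + beta[n]^2
    lam <- (Sb + sqrt(max(n + Sb^2 - n * Sb2, 0))) / n
  }
  n_opt
}

# scalar-loop re-evaluation of the kernel transform chain
transform_oracle <- function(X, zlim = 10) {
  libs <- colSums(X)
  med <- median(libs)
  Xn <- X
  for (j in seq_len(ncol(X))) Xn[, j] <- X[, j] * med / libs[j]
  Xl <- log1p(Xn)
  Z <- Xl * 0
  for (i in seq_len(nrow(X))) {
    m <- mean(Xl[i, ]); s <- sd(Xl[i, ])
    if (s > 0) Z[i, ] <- pmin(pmax((Xl[i, ] - m) / s, -zlim), zlim)
  }
  Z
}

# direct scalar evaluation of the base-2 Jensen-Shannon metric
jsd_oracle <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (x in seq_along(a)) if (a[x] > 0) s <- s + a[x] * log2(a[x] / b[x])
    s
  }
  sqrt(0.5 * (kl(p, m) + kl(q, m)))
}

# hypergeometric upper tail by explicit combinatorial enumeration
hyper_tail_oracle <- function(overlap, size_a, size_b, n) {
  ks <- overlap:min(size_a, size_b)
  sum(choose(size_b, ks) * choose(n - size_b, size_a - ks)) / choose(n, size_a)
}

# adjusted Rand index from the contingency table
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# random probability vector
rprob <- function(len) { x <- rgamma(len, 0.5); x / sum(x) }
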