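# Independent oracles used to verify the package's computations.
# These deliberately use naive, direct formulations (loops, explicit
# combinatorics) so they share no code path with the implementation.

# textbook Pearson correlation of two vectors
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# triple-loop topological overlap
tom_oracle <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  w <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      w[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  w
}

# hypergeometric upper tail P(X >= obs) by direct combinatorial sum
hyper_tail_oracle <- function(obs, N, K, n) {
  lo <- max(obs, 0, n + K - N)
  hi <- min(K, n)
  if (lo > hi) return(0)
  sum(choose(K, lo:hi) * choose(N - K, n - (lo:hi))) / choose(N, n)
}

# probability that g sampled genes co-cluster in a module of size <= m,
# by full enumeration of gene combinations (small n only)
cluster_prob_enum <- function(assign_vec, g, m, unassigned = "grey") {
  combos <- utils::combn(length(assign_vec), g)
  sizes <- table(assign_vec)
  hits <- apply(combos, 2L, function(idx) {
    labs <- assign_vec[idx]
    length(unique(labs)) == 1L && labs[1L] != unassigned &&
      sizes[[labs[1L]]] <= m
  })
  mean(hits)
}

# Pearson chi-square statistic by direct sum((O - E)^2 / E)
chisq_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# random symmetric adjacency with zero diagonal, entries in [0, 1]
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

# random partition for the clustering-test oracle comparisons
random_partition <- function(n, k, seed) {
  set.seed(seed)
  labs <- c(paste0("mod", seq_len(k)), "grey")
  assign_vec <- sample(labs, n, replace = TRUE,
                       prob = c(rep(1, k), 0.5))
  # ensure every module label occurs at least once
  for (i in seq_len(k)) assign_vec[i] <- paste0("mod", i)
  stats::setNames(assign_vec, sprintf("G%04d", seq_len(n)))
}
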