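# Small shared fixtures, all generated in code.

tiny_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_genes = 200, n_celltypes = 3, signatures_per_celltype = 20,
         phenotype_effect = 0.7, noise_sd = 0.5, seed = seed),
    list(...))
  do.call(simulation_config, args)
}

# Independent textbook Pearson correlation: explicit covariance over variance.
oracle_pearson <- function(x, y) {
  n <- length(x)
  cov_xy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  cov_xy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
              sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# Exhaustive hypergeometric upper tail by enumerating all C(N, n) draws from a
# universe whose first B elements are term members.
oracle_hypergeom_tail <- function(b, N, B, n) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= B)
  mean(hits >= b)
}

# Straight-loop mHG scan oracle over every prefix threshold.
oracle_mhg <- function(membership) {
  N <- length(membership)
  B <- sum(membership)
  best <- 1
  n_star <- 0L
  for (n in seq_len(N)) {
    b <- sum(membership[seq_len(n)])
    tail <- sum(stats::dhyper(b:min(n, B), B, N - B, n))
    if (tail < best - 1e-15) {
      best <- tail
      n_star <- n
    }
  }
  list(mhg = best, n_star = n_star)
}
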