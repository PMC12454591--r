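# Independent reference implementations used as oracles ----------------

# permutation reference for Tukey pairwise p-values: permute all labels,
# recompute each pair's Tukey-Kramer studentized range statistic
perm_tukey_ref <- function(groups, B = 1e5) {
  x <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  k <- length(groups)
  N <- length(x)
  gi <- rep(seq_len(k), sizes)
  cmb <- utils::combn(k, 2)
  q_pairs <- function(xp) {           # xp: N x B value matrix
    m <- rowsum(xp, gi) / sizes       # k x B group means
    ssw <- rowsum(xp^2, gi) - sizes * m^2
    s2 <- colSums(ssw) / (N - k)      # pooled within-group variance
    qm <- matrix(0, ncol(cmb), ncol(xp))
    for (j in seq_len(ncol(cmb))) {
      i1 <- cmb[1, j]; i2 <- cmb[2, j]
      qm[j, ] <- abs(m[i1, ] - m[i2, ]) /
        sqrt(s2 / 2 * (1 / sizes[i1] + 1 / sizes[i2]))
    }
    qm
  }
  obs <- q_pairs(matrix(x, N, 1))
  pm <- vapply(seq_len(B), function(b) sample.int(N), integer(N))
  q <- q_pairs(matrix(x[pm], N, B))
  rowMeans(q >= as.vector(obs) - 1e-12)
}

# Monte-Carlo studentized range null: group means N(0, 1/n), pooled
# variance chisq_df/df, balanced one-way layout
mc_q_null <- function(k, n, B = 4e5) {
  m <- matrix(rnorm(k * B, sd = 1 / sqrt(n)), nrow = k)
  df <- k * (n - 1)
  s2 <- rchisq(B, df) / df
  rng <- Reduce(pmax, asplit(m, 1)) - Reduce(pmin, asplit(m, 1))
  rng / sqrt(s2 / n)
}

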