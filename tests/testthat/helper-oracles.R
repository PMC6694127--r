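# Independent brute-force oracles. These deliberately avoid the code paths
# (and the base-R functions) used by the implementation.

# Exact two-sided rank-sum p by full enumeration of all C(n, nx) rank
# assignments: p = min(1, 2 * min(P(W <= w), P(W >= w))).
ranksum_enum_oracle <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  all_w <- apply(utils::combn(length(pooled), nx), 2,
                 function(idx) sum(r[idx]))
  p_low <- mean(all_w <= w_obs)
  p_high <- mean(all_w >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# Hypergeometric upper tail as an explicit binomial-coefficient sum.
hyper_sum_oracle <- function(k, K, N, n) {
  kk <- seq(from = k, to = min(n, K))
  if (k > min(n, K)) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Hypergeometric upper tail by enumerating every n-subset of the universe.
hyper_subset_oracle <- function(k, K, N, n) {
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)  # members 1..K form the set
  mean(overlaps >= k)
}

# KS enrichment score by walking all N profile positions, tracking the
# maximum positive (a) and negative (b) deviations at hit positions.
ks_walk_oracle <- function(gene_set, profile) {
  t_n <- length(gene_set)
  N <- length(profile)
  in_set <- profile %in% gene_set
  j <- 0L
  a <- -Inf
  b <- -Inf
  for (i in seq_len(N)) {
    if (in_set[i]) {
      b <- max(b, i / N - j / t_n)   # before counting this hit
      j <- j + 1L
      a <- max(a, j / t_n - i / N)   # after counting it
    }
  }
  if (a > b) a else -b
}

# Spearman correlation by hand: midranks then the explicit Pearson formula.
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
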