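# Independent brute-force oracles used across tests. These deliberately
# re-derive each statistic from its definition, step by step, so they stay
# independent of the package's vectorized implementations.

# Literal evaluation of the integrated rank-weighted difference statistic:
# walk the descending-expression order position by position.
brute_force_ssgsea <- function(x, gene_set, alpha) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  ord <- order(x, decreasing = TRUE)
  in_set <- names(x) %in% gene_set
  denom_in <- sum(r[in_set]^alpha)
  n_out <- n - sum(in_set)
  es <- 0
  for (i in seq_len(n)) {
    upto <- ord[seq_len(i)]
    p_in <- sum(r[upto[in_set[upto]]]^alpha) / denom_in
    p_out <- sum(!in_set[upto]) / n_out
    es <- es + (p_in - p_out)
  }
  es
}

# Spearman rho and its t-approximation p-value from first principles.
brute_force_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tt), n - 2))
}

# Ordinary pooled two-sample t per feature (oracle for the moderated t
# at d0 = 0).
brute_force_pooled_t <- function(mat, labels) {
  labels <- as.factor(labels)
  g1 <- labels == levels(labels)[1]
  apply(mat, 1, function(v) {
    x <- v[g1]; y <- v[!g1]
    sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
      (length(x) + length(y) - 2)
    (mean(y) - mean(x)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  })
}

# Small standardized helper: a tiny planted-block metabolome for network
# tests (3 blocks of 15, within-correlation 0.8, no trait linkage).
three_block_metabolome <- function(seed = 1, n = 100) {
  simulate_metabolome_cohort(metabolome_sim_config(
    n_gc = n, n_healthy = 0, n_metabolites = 45,
    module_spec = list(
      list(size = 15, within_correlation = 0.8, trait_correlation = 0),
      list(size = 15, within_correlation = 0.8, trait_correlation = 0),
      list(size = 15, within_correlation = 0.8, trait_correlation = 0)),
    dem_spec = list(), seed = seed))
}
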