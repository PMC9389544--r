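## Single-sample gene-set enrichment scoring (Barbie-style integrated
## rank-weighted difference statistic), top/bottom grouping, two-group
## GSEA with permutation NES/p, and trait-score correlation.

#' ssGSEA parameters
#' @param alpha rank-weight exponent (default 0.25, the conventional
#'   choice).
#' @param normalize divide all enrichment scores by the global
#'   `max - min` of the score matrix (default `TRUE`).
#' @return List of class `ssgsea_params`.
#' @export
ssgsea_params <- function(alpha = 0.25, normalize = TRUE) {
  if (alpha < 0) stop("alpha must be >= 0")
  structure(list(alpha = alpha, normalize = normalize),
            class = "ssgsea_params")
}

#' Single-sample enrichment score for one gene set
#'
#' Genes are ranked by descending expression (mid-ranks for ties; the walk
#' order breaks ties by input position). With rank weights `r` running
#' from N down to 1, the score is the integrated difference
#' `ES = sum_i [P_in^w(i) - P_out(i)]` where `P_in^w` accumulates
#' `r^alpha` over in-set genes and `P_out` is the empirical CDF of
#' out-of-set genes.
#'
#' @param sample_expression named numeric vector over genes (>= 2 genes).
#' @param gene_set character vector of member ids; the intersection with
#'   the expression genes must be non-empty and proper.
#' @param params an [ssgsea_params()].
#' @return The enrichment score (a real number).
#' @export
ssgsea_es <- function(sample_expression, gene_set,
                      params = ssgsea_params()) {
  x <- sample_expression
  n <- length(x)
  if (n < 2) stop("need >= 2 genes")
  in_set <- names(x) %in% gene_set
  if (!any(in_set))
    stop("gene set has no overlap with the expression genes: ",
         paste(head(gene_set, 3), collapse = ", "))
  if (all(in_set)) stop("gene set covers all genes; P_out undefined")
  r <- rank(x, ties.method = "average")  # top gene gets rank N
  ord <- order(x, decreasing = TRUE)     # stable: ties keep input order
  w <- r[ord]^params$alpha
  w[!in_set[ord]] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_set[ord]) / (n - sum(in_set))
  sum(p_in - p_out)
}

#' ssGSEA score matrix over gene sets and samples
#'
#' @param expr genes x samples log2 expression matrix.
#' @param sets named list of gene sets; sets with no overlap are dropped
#'   with a warning.
#' @param params an [ssgsea_params()]; with `normalize = TRUE` every score
#'   is divided by the global `max - min` of the matrix.
#' @return sets x samples numeric matrix of scores.
#' @export
ssgsea_matrix <- function(expr, sets, params = ssgsea_params()) {
  stop_if_not_numeric_matrix(expr, "expr")
  overlap <- vapply(sets, function(s) {
    k <- sum(rownames(expr) %in% s)
    k > 0 && k < nrow(expr)
  }, logical(1))
  if (!all(overlap)) {
    if (!any(overlap)) stop("all gene sets were dropped (no usable overlap)")
    warning("dropping set(s) with no usable overlap: ",
            paste(names(sets)[!overlap], collapse = ", "))
    sets <- sets[overlap]
  }
  scores <- matrix(NA_real_, length(sets), ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    names(x) <- rownames(expr)
    for (s in seq_along(sets))
      scores[s, j] <- ssgsea_es(x, sets[[s]], params)
  }
  if (params$normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  scores
}

#' Split samples into top and bottom fractions of a score
#'
#' @param values named per-sample scalar (e.g. a gene's expression or a
#'   pathway score).
#' @param fraction fraction per tail (default 0.3, i.e. top 30% and
#'   bottom 30%); `floor(fraction * n)` must be >= 1.
#' @return List with `high` and `low` sample id vectors. Ties are broken
#'   by input order (a warning is emitted when all values are equal).
#' @export
partition_high_low <- function(values, fraction = 0.3) {
  n <- length(values)
  k <- floor(fraction * n)
  if (k < 1) stop("floor(fraction * n) must be >= 1")
  if (length(unique(values)) == 1)
    warning("all values equal; partition falls back to input order")
  ids <- names(values) %||% as.character(seq_len(n))
  ord <- order(values, decreasing = TRUE)  # stable for ties
  list(high = ids[ord[seq_len(k)]],
       low = ids[rev(ord)[seq_len(k)]][k:1])
}

weighted_ks_es <- function(stat_sorted, in_set_sorted) {
  n <- length(stat_sorted)
  nh <- sum(in_set_sorted)
  w <- abs(stat_sorted)
  w[!in_set_sorted] <- 0
  p_hit <- cumsum(w) / sum(w)
  p_miss <- cumsum(!in_set_sorted) / (n - nh)
  dev <- p_hit - p_miss
  dev[which.max(abs(dev))]
}

#' Two-group GSEA with permutation-based NES and p-values
#'
#' Genes are ranked by the moderated t of high vs low; the enrichment
#' score is the maximum deviation of the weighted Kolmogorov-Smirnov
#' running sum (weight `|t|`). Significance comes from sample-label
#' permutations: `NES = ES / mean(|permutation ES of the same sign|)` and
#' the p-value is the permutation tail frequency within the same-sign
#' pool, with BH adjustment across sets.
#'
#' @param expr genes x samples matrix.
#' @param group_high,group_low sample ids of the two groups (>= 3 each).
#' @param sets named list of gene sets.
#' @param n_perm number of label permutations (default 1000; < 100 warns).
#' @param seed RNG seed for the permutations.
#' @return A data.frame of class `gsea_result` with `set`, `size`, `es`,
#'   `nes`, `p`, `q`.
#' @export
gsea_two_group <- function(expr, group_high, group_low, sets,
                           n_perm = 1000, seed = 1L) {
  stop_if_not_numeric_matrix(expr, "expr")
  if (length(group_high) < 3 || length(group_low) < 3)
    stop("each group needs >= 3 samples")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value grid")
  sub <- expr[, c(group_high, group_low), drop = FALSE]
  labels <- factor(rep(c("high", "low"),
                       c(length(group_high), length(group_low))),
                   levels = c("low", "high"))
  t_obs <- moderated_t_two_group(sub, labels)$table$t
  if (length(unique(t_obs)) == 1)
    stop("degenerate ranking: all gene statistics equal")
  names(t_obs) <- rownames(sub)
  overlap <- vapply(sets, function(s) {
    k <- sum(rownames(sub) %in% s)
    k > 0 && k < nrow(sub)
  }, logical(1))
  if (!all(overlap)) {
    if (!any(overlap)) stop("all gene sets were dropped (no usable overlap)")
    warning("dropping set(s) with no usable overlap: ",
            paste(names(sets)[!overlap], collapse = ", "))
    sets <- sets[overlap]
  }
  in_set <- lapply(sets, function(s) rownames(sub) %in% s)
  es_from_t <- function(tt) {
    ord <- order(tt, decreasing = TRUE)
    vapply(in_set, function(m) weighted_ks_es(tt[ord], m[ord]), numeric(1))
  }
  es <- es_from_t(t_obs)
  set.seed(seed)
  perm_es <- matrix(NA_real_, n_perm, length(sets))
  for (b in seq_len(n_perm)) {
    pl <- sample(labels)
    tp <- moderated_t_two_group(sub, pl)$table$t
    names(tp) <- rownames(sub)
    perm_es[b, ] <- es_from_t(tp)
  }
  nes <- p <- numeric(length(sets))
  for (s in seq_along(sets)) {
    pool <- perm_es[sign(perm_es[, s]) == sign(es[s]), s]
    if (!length(pool)) pool <- abs(perm_es[, s])
    nes[s] <- es[s] / mean(abs(pool))
    p[s] <- (1 + sum(abs(pool) >= abs(es[s]))) / (1 + length(pool))
  }
  out <- data.frame(set = names(sets),
                    size = vapply(in_set, sum, numeric(1)),
                    es = es, nes = nes, p = p,
                    q = benjamini_hochberg(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("gsea_result", "data.frame"),
            n_perm = n_perm, seed = seed)
}

#' Spearman correlation of a per-sample feature with each score row
#'
#' @param feature_values named per-sample scalar (e.g. ERBB2 expression or
#'   an HER2 protein level); must be non-constant.
#' @param scores sets x samples score matrix (see [ssgsea_matrix()]).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Data.frame with `set`, `rho`, `p` (t approximation) and BH `q`.
#' @export
score_trait_correlation <- function(feature_values, scores,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  common <- intersect(names(feature_values), colnames(scores))
  if (length(common) < 4) stop("need >= 4 paired observations")
  f <- feature_values[common]
  if (length(unique(f)) == 1) stop("constant feature vector; rho undefined")
  if (method == "spearman") f <- rank(f)
  res <- t(apply(scores[, common, drop = FALSE], 1, function(sc) {
    s <- if (method == "spearman") rank(sc) else sc
    n <- length(s)
    rho <- cor(f, s)
    if (is.na(rho)) return(c(rho = NA_real_, p = NA_real_))
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    c(rho = rho, p = 2 * pt(-abs(tt), n - 2))
  }))
  data.frame(set = rownames(scores), rho = res[, "rho"], p = res[, "p"],
             q = benjamini_hochberg(res[, "p"]),
             row.names = NULL, stringsAsFactors = FALSE)
}
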