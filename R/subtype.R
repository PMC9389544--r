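## Consensus clustering of pathway genes, coexpressed-group selection,
## median-score quadrant subtyping, subtype-specific molecules, k-group
## feature tests and subtype survival comparison.

#' Restrict an expression matrix to a pathway gene set
#'
#' @param expr genes x samples matrix.
#' @param genes character vector of pathway gene ids (order preserved).
#' @return Submatrix of the found genes; attribute `missing_genes` lists
#'   absent ids. Errors when the intersection is empty.
#' @export
subset_pathway_genes <- function(expr, genes) {
  found <- genes[genes %in% rownames(expr)]
  if (!length(found))
    stop("no pathway genes found in the expression matrix (first ids: ",
         paste(head(genes, 3), collapse = ", "), ")")
  out <- expr[found, , drop = FALSE]
  attr(out, "missing_genes") <- setdiff(genes, found)
  out
}

#' Consensus clustering parameters
#'
#' Defaults follow the conventional resampled consensus run: k = 3,
#' 100 resampling repetitions, 80% item sampling, all features, Ward
#' linkage on 1 - Pearson correlation distance.
#'
#' @param k,reps,p_item,p_feature,seed see Details.
#' @return List of class `consensus_params`.
#' @export
consensus_params <- function(k = 3, reps = 100, p_item = 0.8,
                             p_feature = 1.0, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  if (reps < 1) stop("reps must be >= 1")
  if (p_item <= 0 || p_item > 1) stop("p_item must be in (0, 1]")
  if (p_feature <= 0 || p_feature > 1) stop("p_feature must be in (0, 1]")
  structure(list(k = k, reps = reps, p_item = p_item,
                 p_feature = p_feature, seed = seed),
            class = "consensus_params")
}

ward_cor_cluster <- function(x, k) {
  ## items are rows; Ward.D2 linkage on 1 - Pearson correlation distance
  d <- stats::as.dist(1 - cor(t(x)))
  cutree(hclust(d, method = "ward.D2"), k = k)
}

#' Monti-style consensus clustering of items
#'
#' Repeated subsampling (`p_item` of the items, `p_feature` of the
#' features, without replacement), inner Ward.D2 clustering on 1 - Pearson
#' distance cut at k, and a consensus matrix
#' `M_ij = co-clustered(i, j) / co-sampled(i, j)` (0/0 counted as 0).
#' Final labels come from Ward.D2 clustering of `1 - M` cut at k.
#'
#' @param x items x features matrix (here: genes x samples).
#' @param params a [consensus_params()].
#' @return A `consensus_result`: `consensus` matrix, `labels` (named),
#'   `co_sampled` counts, `per_cluster_consensus`, and `params`.
#' @export
consensus_cluster <- function(x, params = consensus_params()) {
  stop_if_not_numeric_matrix(x, "x")
  n <- nrow(x)
  if (params$k > n) stop("k exceeds the number of items")
  if (ncol(x) < 4) stop("need >= 4 features (samples)")
  set.seed(params$seed)
  n_item <- ceiling(params$p_item * n)
  n_feat <- ceiling(params$p_feature * ncol(x))
  connected <- cosampled <- matrix(0, n, n)
  for (b in seq_len(params$reps)) {
    items <- sort(sample.int(n, n_item))
    feats <- if (n_feat < ncol(x)) sort(sample.int(ncol(x), n_feat))
    else seq_len(ncol(x))
    kb <- min(params$k, length(items))  # resample may hold fewer items
    cl <- if (length(items) == 1) 1L
    else ward_cor_cluster(x[items, feats, drop = FALSE], kb)
    ind <- matrix(0L, n, kb)
    ind[cbind(items, cl)] <- 1L
    connected <- connected + ind %*% t(ind)
    samp <- integer(n); samp[items] <- 1L
    cosampled <- cosampled + outer(samp, samp)
  }
  consensus <- ifelse(cosampled > 0, connected / cosampled, 0)
  diag(consensus) <- 1
  dimnames(consensus) <- list(rownames(x), rownames(x))
  labels <- cutree(hclust(stats::as.dist(1 - consensus),
                          method = "ward.D2"), k = params$k)
  names(labels) <- rownames(x)
  per_cluster <- vapply(seq_len(params$k), function(c) {
    idx <- which(labels == c)
    if (length(idx) < 2) return(NA_real_)
    m <- consensus[idx, idx]
    mean(m[upper.tri(m)])
  }, numeric(1))
  structure(list(consensus = consensus, labels = labels,
                 co_sampled = cosampled,
                 per_cluster_consensus = per_cluster, params = params),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering: k =", x$params$k, "over",
      nrow(x$consensus), "items,", x$params$reps, "reps\n")
  cat("  cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  cat("  mean within-cluster consensus:",
      paste(signif(x$per_cluster_consensus, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Select the strongly coexpressed gene cluster
#'
#' From a k-level gene clustering, return the cluster with the highest
#' mean pairwise signed Pearson correlation among its members; ties are
#' broken towards the larger cluster, then the lowest label. Singleton
#' clusters carry no coexpression evidence and are skipped (an error is
#' raised if all clusters are singletons).
#'
#' @param x genes x samples matrix.
#' @param labels named cluster labels over the genes (e.g. from
#'   [consensus_cluster()]).
#' @return Character vector of the selected cluster's gene ids.
#' @export
select_coexpressed_group <- function(x, labels) {
  labels <- labels[rownames(x)]
  cl <- sort(unique(labels))
  mean_r <- vapply(cl, function(c) {
    idx <- which(labels == c)
    if (length(idx) < 2) return(NA_real_)
    r <- cor(t(x[idx, , drop = FALSE]))
    mean(r[upper.tri(r)])
  }, numeric(1))
  if (all(is.na(mean_r)))
    stop("all clusters are singletons; no coexpression evidence")
  sizes <- as.integer(table(factor(labels, levels = cl)))
  ord <- order(-mean_r, -sizes, cl, na.last = TRUE)
  best <- cl[ord[1]]
  names(labels)[labels == best]
}

#' Per-sample pathway score: median of z-scored selected genes
#'
#' Each selected gene is z-scored across samples; the pathway score of a
#' sample is the median z over the selected genes. A score of 0 therefore
#' marks cohort-average pathway expression, which is what the quadrant
#' rule thresholds.
#'
#' @param expr genes x samples matrix (>= 2 samples).
#' @param selected_genes gene ids to aggregate.
#' @return Named per-sample score vector.
#' @export
pathway_score <- function(expr, selected_genes) {
  if (ncol(expr) < 2) stop("z-scores need >= 2 samples")
  sub <- subset_pathway_genes(expr, selected_genes)
  z <- standardize_rows(sub)
  apply(z, 2, median)
}

#' Assign quadrant metabolic subtypes from two pathway scores
#'
#' The exact quadrant rule with boundaries on the `<=` side:
#' quiescent (AAG <= 0, GG <= 0), AAG (AAG > 0, GG <= 0),
#' GG (AAG <= 0, GG > 0), mixed (AAG > 0, GG > 0).
#'
#' @param aag_scores,gg_scores named per-sample scores (matching ids).
#' @return A data.frame of class `subtype_scores` with `sample_id`,
#'   `aag_score`, `gg_score`, `subtype` (factor
#'   quiescent/AAG/GG/mixed). Samples missing either score are excluded
#'   with a warning.
#' @export
assign_subtypes <- function(aag_scores, gg_scores) {
  ids <- intersect(names(aag_scores), names(gg_scores))
  dropped <- length(union(names(aag_scores), names(gg_scores))) - length(ids)
  a <- aag_scores[ids]; g <- gg_scores[ids]
  keep <- !is.na(a) & !is.na(g)
  dropped <- dropped + sum(!keep)
  if (dropped > 0)
    warning(dropped, " sample(s) without both scores excluded")
  a <- a[keep]; g <- g[keep]; ids <- ids[keep]
  subtype <- ifelse(a > 0,
                    ifelse(g > 0, "mixed", "AAG"),
                    ifelse(g > 0, "GG", "quiescent"))
  structure(data.frame(sample_id = ids, aag_score = unname(a),
                       gg_score = unname(g),
                       subtype = factor(subtype,
                                        levels = c("quiescent", "AAG",
                                                   "GG", "mixed")),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("subtype_scores", "data.frame"))
}

#' @export
write_results.subtype_scores <- function(x, path, format = "json", ...) {
  if (format == "json") {
    jsonlite::write_json(as.list(setNames(as.character(x$subtype),
                                          x$sample_id)),
                         path, auto_unbox = TRUE)
  } else if (format == "tsv") {
    write_results.data.frame(as.data.frame(x), path, "tsv")
  } else stop("unsupported (subtype_scores, ", format,
              "); supported: json, tsv")
  invisible(path)
}

#' Full two-pathway consensus subtyping pipeline
#'
#' Chains [subset_pathway_genes()], [consensus_cluster()] (per pathway),
#' [select_coexpressed_group()], [pathway_score()] and
#' [assign_subtypes()].
#'
#' @param expr genes x samples log2 expression matrix.
#' @param aag_set,gg_set pathway gene-id vectors (e.g. the KEGG
#'   alanine-aspartate-glutamate and glycolysis/gluconeogenesis sets).
#' @param params a [consensus_params()].
#' @return A `metabolic_subtype` list: per-pathway `consensus` results and
#'   `selected` gene vectors, the `scores` data.frame
#'   ([assign_subtypes()]) and `params`.
#' @export
metabolic_subtype <- function(expr, aag_set, gg_set,
                              params = consensus_params()) {
  run_pathway <- function(set, seed_offset) {
    sub <- subset_pathway_genes(expr, set)
    p <- params
    p$seed <- params$seed + seed_offset
    cc <- consensus_cluster(sub, p)
    sel <- select_coexpressed_group(sub, cc$labels)
    list(consensus = cc, selected = sel,
         scores = pathway_score(expr, sel))
  }
  aag <- run_pathway(aag_set, 0L)
  gg <- run_pathway(gg_set, 1L)
  scores <- assign_subtypes(aag$scores, gg$scores)
  structure(list(aag = aag, gg = gg, scores = scores, params = params),
            class = "metabolic_subtype")
}

#' @export
print.metabolic_subtype <- function(x, ...) {
  cat("Two-pathway quadrant metabolic subtyping\n")
  cat("  coexpressed genes: AAG", length(x$aag$selected),
      "/ GG", length(x$gg$selected), "\n")
  print(table(x$scores$subtype))
  invisible(x)
}

#' @export
plot.metabolic_subtype <- function(x, ...) {
  cols <- c(quiescent = "grey50", AAG = "#D55E00", GG = "#0072B2",
            mixed = "#009E73")
  plot(x$scores$gg_score, x$scores$aag_score,
       col = cols[as.character(x$scores$subtype)], pch = 16,
       xlab = "GG median z-score", ylab = "AAG median z-score", ...)
  abline(h = 0, v = 0, lty = 2)
  legend("topleft", legend = names(cols), col = cols, pch = 16, bty = "n")
  invisible(x)
}

#' Subtype-specific molecules
#'
#' A feature (mRNA, miRNA, lncRNA...) is specific to a subtype when it is
#' significantly upregulated against every other subtype: log2fc > 0 and
#' BH FDR < `fdr_max` in each pairwise moderated-t comparison (FDR taken
#' across features within each comparison).
#'
#' @param expr features x samples matrix.
#' @param labels named subtype labels over samples; subtypes with < 2
#'   samples are excluded from comparisons with a warning.
#' @param fdr_max per-comparison FDR threshold (default 0.05).
#' @return A `specific_molecules` list: per subtype, a character vector of
#'   specific feature ids; attribute `comparisons` counts the pairwise
#'   tests run.
#' @export
specific_molecules <- function(expr, labels, fdr_max = 0.05) {
  labels <- labels[colnames(expr)]
  tab <- table(labels)
  usable <- names(tab)[tab >= 2]
  if (length(usable) < length(tab))
    warning("subtype(s) with < 2 samples excluded: ",
            paste(setdiff(names(tab), usable), collapse = ", "))
  if (length(usable) < 2) stop("need >= 2 usable subtypes")
  result <- list()
  n_comp <- 0
  for (s in usable) {
    others <- setdiff(usable, s)
    ok <- rep(TRUE, nrow(expr))
    for (o in others) {
      cols <- labels %in% c(s, o)
      fit <- moderated_t_two_group(expr[, cols, drop = FALSE],
                                   factor(labels[cols],
                                          levels = c(o, s)))
      q <- benjamini_hochberg(fit$table$p)
      ok <- ok & fit$table$log2fc > 0 & q < fdr_max
      n_comp <- n_comp + 1
    }
    result[[s]] <- rownames(expr)[ok]
  }
  structure(result, class = "specific_molecules", comparisons = n_comp)
}

#' @export
print.specific_molecules <- function(x, ...) {
  cat("Subtype-specific molecules:\n")
  for (s in names(x)) cat(" ", s, ":", length(x[[s]]), "\n")
  invisible(x)
}

#' Per-feature Kruskal-Wallis tests across subtypes
#'
#' @param feature_matrix features x samples matrix (genes, checkpoint
#'   genes, or immune scores).
#' @param labels named subtype labels over samples.
#' @param p_max strict retention threshold (default 0.05).
#' @return A data.frame with `id`, `statistic`, `p` and logical
#'   `retained`; attribute `retained_ids` lists the filtered set.
#' @export
subtype_group_tests <- function(feature_matrix, labels, p_max = 0.05) {
  labels <- labels[colnames(feature_matrix)]
  res <- t(apply(feature_matrix, 1, function(v) {
    kw <- kruskal_wallis(split(v, labels))
    c(statistic = kw$statistic, p = kw$p.value)
  }))
  out <- data.frame(id = rownames(feature_matrix),
                    statistic = res[, "statistic"], p = res[, "p"],
                    retained = res[, "p"] < p_max,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "retained_ids") <- out$id[out$retained]
  out
}

#' Survival comparison across metabolic subtypes
#'
#' Excludes exactly the samples with a missing time or event for the
#' chosen endpoint, then computes a Kaplan-Meier curve per subtype and the
#' k-group log-rank test.
#'
#' @param clinical clinical data.frame with `sample_id`, `os_time`,
#'   `os_event` (and/or `dss_time`, `dss_event`).
#' @param labels named subtype labels (names = sample ids).
#' @param endpoint `"OS"` (default) or `"DSS"`.
#' @return A `subtype_survival` list: `curves` (one [km_curve()] per
#'   subtype), `test` (log-rank `mbs_test`), `n_used`, `n_excluded`.
#' @export
subtype_survival <- function(clinical, labels, endpoint = c("OS", "DSS")) {
  endpoint <- match.arg(endpoint)
  tcol <- if (endpoint == "OS") "os_time" else "dss_time"
  ecol <- if (endpoint == "OS") "os_event" else "dss_event"
  if (!all(c(tcol, ecol) %in% colnames(clinical)))
    stop("clinical table lacks ", tcol, "/", ecol)
  idx <- match(clinical$sample_id, names(labels))
  keep <- !is.na(idx) & !is.na(clinical[[tcol]]) & !is.na(clinical[[ecol]])
  if (!any(keep)) stop("no samples with follow-up information")
  cl <- clinical[keep, ]
  grp <- factor(labels[cl$sample_id])
  grp <- droplevels(grp)
  if (nlevels(grp) < 2) stop("need >= 2 subtypes with follow-up")
  curves <- lapply(levels(grp), function(l)
    km_curve(cl[[tcol]][grp == l], cl[[ecol]][grp == l]))
  names(curves) <- levels(grp)
  test <- logrank_test(cl[[tcol]], cl[[ecol]], grp)
  structure(list(curves = curves, test = test, endpoint = endpoint,
                 n_used = sum(keep), n_excluded = sum(!keep)),
            class = "subtype_survival")
}

#' @export
print.subtype_survival <- function(x, ...) {
  cat(x$endpoint, "survival across", length(x$curves), "subtypes (",
      x$n_used, "used,", x$n_excluded, "excluded )\n")
  print(x$test)
  invisible(x)
}

#' @export
plot.subtype_survival <- function(x, col = seq_along(x$curves), ...) {
  tmax <- max(unlist(lapply(x$curves, function(c)
    c(c$time, c$censor_times))), na.rm = TRUE)
  plot(NA, xlim = c(0, tmax), ylim = c(0, 1),
       xlab = paste(x$endpoint, "time"), ylab = "survival", ...)
  for (i in seq_along(x$curves)) {
    c <- x$curves[[i]]
    tt <- c(0, rep(c$time, each = 2), tmax)
    ss <- c(1, 1, rep(c$survival, each = 2))
    lines(tt, ss[seq_along(tt)], col = col[i])
  }
  legend("bottomleft", legend = names(x$curves), col = col, lty = 1,
         bty = "n")
  invisible(x)
}
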