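## Weighted metabolite co-expression network analysis: soft-threshold
## selection by scale-free fit, unsigned adjacency, topological overlap,
## static-cut module detection, eigenmetabolites, module-trait statistics
## and hub-metabolite selection against an ordinal HER2 IHC trait.

#' Log2-standardize a metabolite abundance matrix
#'
#' log2-transform and z-score each metabolite across samples; the
#' standardized scale is what the network correlations, eigenmetabolites
#' and MMI network operate on. Zero-variance metabolites are dropped with
#' a warning.
#'
#' @param abundance positive metabolites x samples matrix.
#' @param log2 apply log2 first (set `FALSE` if already log-scale).
#' @return Standardized metabolites x samples matrix.
#' @export
standardize_metabolome <- function(abundance, log2 = TRUE) {
  stop_if_not_numeric_matrix(abundance, "abundance")
  x <- if (log2) base::log2(abundance) else abundance
  s <- apply(x, 1, sd)
  if (any(s == 0)) {
    warning("dropping ", sum(s == 0), " zero-variance metabolite(s): ",
            paste(head(rownames(x)[s == 0], 5), collapse = ", "))
    x <- x[s > 0, , drop = FALSE]
    s <- s[s > 0]
  }
  (x - rowMeans(x)) / s
}

#' Pearson correlation matrix between metabolites
#'
#' @param abundance positive metabolites x samples matrix (>= 4 samples);
#'   values are log2-transformed and standardized internally.
#' @param log2 passed to [standardize_metabolome()].
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
metabolite_correlation <- function(abundance, log2 = TRUE) {
  if (ncol(abundance) < 4) stop("need >= 4 samples")
  z <- standardize_metabolome(abundance, log2 = log2)
  r <- cor(t(z))
  diag(r) <- 1
  r
}

#' Unsigned soft-threshold adjacency
#'
#' `A_ij = |r_ij|^power` off the diagonal, `A_ii = 0`.
#'
#' @param cor_matrix symmetric correlation matrix.
#' @param power soft-thresholding exponent (>= 1).
#' @return Adjacency matrix.
#' @export
adjacency_matrix <- function(cor_matrix, power) {
  if (power < 1) stop("power must be >= 1")
  a <- abs(cor_matrix)^power
  diag(a) <- 0
  a
}

#' Scan soft-thresholding powers for scale-free topology
#'
#' For each power the connectivities `k_i = sum_j |r_ij|^power` are binned
#' into 10 equal-width bins and `log10(frequency)` is regressed on
#' `log10(mean k)` over non-empty bins; the signed scale-free fit is
#' `-sign(slope) * R^2`. The chosen power is the smallest one whose signed
#' fit reaches `rsq_target`.
#'
#' @param cor_matrix correlation matrix over >= 20 nodes.
#' @param powers candidate integer powers (default 1..20).
#' @param rsq_target signed R-squared target (default 0.85).
#' @param n_bins connectivity histogram bins (default 10).
#' @return A `soft_threshold_scan`: data.frame `fit` with `power`,
#'   `signed_rsq`, `mean_connectivity`, plus `chosen_power` (NA when no
#'   power reaches the target).
#' @export
soft_threshold_scan <- function(cor_matrix, powers = 1:20,
                                rsq_target = 0.85, n_bins = 10) {
  if (nrow(cor_matrix) < 20) stop("need >= 20 nodes for a scale-free fit")
  fit <- data.frame(power = powers, signed_rsq = NA_real_,
                    mean_connectivity = NA_real_)
  for (i in seq_along(powers)) {
    a <- adjacency_matrix(cor_matrix, powers[i])
    k <- rowSums(a)
    fit$mean_connectivity[i] <- mean(k)
    fit$signed_rsq[i] <- scale_free_fit(k, n_bins)
  }
  ok <- which(!is.na(fit$signed_rsq) & fit$signed_rsq >= rsq_target)
  structure(list(fit = fit,
                 chosen_power = if (length(ok)) powers[min(ok)] else
                   NA_integer_,
                 rsq_target = rsq_target),
            class = "soft_threshold_scan")
}

scale_free_fit <- function(k, n_bins = 10) {
  if (max(k) == min(k)) return(NA_real_)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & mean_k > 0
  if (sum(keep) < 3) return(NA_real_)
  lx <- log10(mean_k[keep])
  ly <- log10(freq[keep])
  f <- stats::lm(ly ~ lx)
  r2 <- summary(f)$r.squared
  -sign(stats::coef(f)[2]) * r2
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat("Soft-threshold scan (target signed R^2 >=", x$rsq_target, ")\n")
  if (is.na(x$chosen_power)) cat("  no power reached the target\n")
  else {
    row <- x$fit[x$fit$power == x$chosen_power, ]
    cat(sprintf("  chosen power %d (signed R^2 = %.3f, mean k = %.2f)\n",
                x$chosen_power, row$signed_rsq, row$mean_connectivity))
  }
  invisible(x)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u A_iu A_uj + A_ij) / (min(k_i, k_j) + 1 - A_ij)` with
#' unit diagonal; the clustering dissimilarity is `1 - TOM`.
#'
#' @param adjacency symmetric matrix with entries in \[0, 1\] and zero
#'   diagonal.
#' @return TOM similarity matrix.
#' @export
tom_matrix <- function(adjacency) {
  if (any(adjacency < 0 | adjacency > 1)) stop("adjacency must be in [0,1]")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be 0")
  k <- rowSums(adjacency)
  num <- adjacency %*% adjacency + adjacency
  den <- outer(k, k, pmin) + 1 - adjacency
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Detect metabolite modules by average-linkage clustering of 1 - TOM
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity with a
#' deterministic static cut (the `cutreeStatic` convention): branches are
#' severed at the absolute height `cut_quantile` on the unit-interval TOM
#' dissimilarity scale, so tightly overlapping metabolites (dissimilarity
#' well below the cut) stay together while unrelated ones (dissimilarity
#' near 1) fall apart into unassigned singletons. Clusters smaller than
#' `min_module_size` are left unassigned (module 0). Modules are numbered
#' by decreasing size.
#'
#' @param diss_tom dissimilarity matrix (`1 - TOM`, entries in \[0, 1\]).
#' @param min_module_size smallest retained module (>= 2; default 5).
#' @param cut_quantile absolute static cut height on the \[0, 1\]
#'   dissimilarity scale (default 0.92).
#' @return A `module_partition`: named integer vector `module` (0 =
#'   unassigned), `sizes`, and the `hclust` tree.
#' @export
detect_modules <- function(diss_tom, min_module_size = 5,
                           cut_quantile = 0.92) {
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  tree <- hclust(stats::as.dist(diss_tom), method = "average")
  cl <- if (cut_quantile >= max(tree$height))
    setNames(rep(1L, length(tree$order)), tree$labels)
  else cutree(tree, h = cut_quantile)
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  module <- integer(length(cl))
  if (length(keep)) {
    kept_sizes <- sizes[as.character(keep)]
    relabel <- setNames(rank(-kept_sizes, ties.method = "first"),
                        as.character(keep))
    assigned <- cl %in% keep
    module[assigned] <- relabel[as.character(cl[assigned])]
  }
  names(module) <- rownames(diss_tom)
  structure(list(module = module,
                 sizes = table(module[module > 0]),
                 n_unassigned = sum(module == 0),
                 tree = tree,
                 min_module_size = min_module_size,
                 cut_quantile = cut_quantile),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("Module partition:", length(x$sizes), "module(s),",
      x$n_unassigned, "unassigned of", length(x$module), "metabolites\n")
  if (length(x$sizes))
    cat("  sizes:", paste(as.integer(x$sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Module eigenmetabolites
#'
#' First principal component of each module's standardized member profiles
#' (samples x members), scaled to unit variance and sign-oriented to
#' correlate positively with the module's mean profile. A single-member
#' module returns that metabolite's standardized profile.
#'
#' @param z standardized metabolites x samples matrix
#'   (see [standardize_metabolome()]).
#' @param partition a [detect_modules()] result (or a named module
#'   vector).
#' @return samples x modules matrix of eigenmetabolite values.
#' @export
module_eigenmetabolites <- function(z, partition) {
  module <- if (inherits(partition, "module_partition")) partition$module
  else partition
  mods <- sort(unique(module[module > 0]))
  if (!length(mods)) stop("no assigned modules")
  eig <- matrix(NA_real_, ncol(z), length(mods),
                dimnames = list(colnames(z), paste0("ME", mods)))
  for (i in seq_along(mods)) {
    members <- names(module)[module == mods[i]]
    xm <- t(z[members, , drop = FALSE])  # samples x members
    e <- if (ncol(xm) == 1) xm[, 1] else prcomp(xm, center = FALSE,
                                                scale. = FALSE)$x[, 1]
    e <- e / sd(e)
    if (cor(e, rowMeans(xm)) < 0) e <- -e
    eig[, i] <- e
  }
  eig
}

#' Module-trait statistics: eigenmetabolite correlations, MM and MES
#'
#' Module-level: Pearson correlation (with t-approximation p) of each
#' eigenmetabolite with the trait. Metabolite-level: module membership
#' `MM = |cor(metabolite, own module eigenmetabolite)|` and metabolite
#' significance `MES = |cor(metabolite, trait)|`. Samples with a missing
#' trait are dropped pairwise; the ordinal HER2 IHC score (0-3) is treated
#' numerically by default.
#'
#' @param z standardized metabolites x samples matrix.
#' @param partition a [detect_modules()] result.
#' @param eigens eigenmetabolite matrix from [module_eigenmetabolites()].
#' @param trait named per-sample numeric trait (e.g. HER2 IHC 0-3),
#'   non-constant, >= 4 complete pairs.
#' @param method correlation type, `"pearson"` (default) or `"spearman"`.
#' @return A `module_trait_stats` list: `module_stats` (module, size, r,
#'   p) and `metabolite_stats` (id, module, MM, MES).
#' @export
module_trait_stats <- function(z, partition, eigens, trait,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  module <- partition$module
  common <- intersect(colnames(z), names(trait)[!is.na(trait)])
  if (length(common) < 4) stop("need >= 4 complete trait pairs")
  tr <- trait[common]
  if (length(unique(tr)) == 1) stop("trait is constant")
  if (method == "spearman") tr <- rank(tr)
  cor_p <- function(a, b) {
    rho <- cor(a, b)
    n <- length(a)
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    c(r = rho, p = 2 * pt(-abs(tt), n - 2))
  }
  mods <- sort(unique(module[module > 0]))
  ms <- t(vapply(mods, function(m) {
    e <- eigens[common, paste0("ME", m)]
    cor_p(if (method == "spearman") rank(e) else e, tr)
  }, c(r = 0, p = 0)))
  module_stats <- data.frame(module = mods,
                             size = as.integer(table(module[module > 0])),
                             r = ms[, "r"], p = ms[, "p"],
                             row.names = NULL)
  mm <- mes <- rep(NA_real_, nrow(z))
  for (i in seq_len(nrow(z))) {
    prof <- z[i, common]
    if (method == "spearman") prof <- rank(prof)
    mes[i] <- abs(cor(prof, tr))
    m <- module[rownames(z)[i]]
    if (!is.na(m) && m > 0) {
      e <- eigens[common, paste0("ME", m)]
      mm[i] <- abs(cor(z[i, common], e))
    }
  }
  metabolite_stats <- data.frame(id = rownames(z),
                                 module = unname(module[rownames(z)]),
                                 MM = mm, MES = mes,
                                 row.names = NULL, stringsAsFactors = FALSE)
  structure(list(module_stats = module_stats,
                 metabolite_stats = metabolite_stats,
                 method = method, n_pairs = length(common)),
            class = "module_trait_stats")
}

#' @export
print.module_trait_stats <- function(x, ...) {
  cat("Module-trait statistics (", x$method, ", ", x$n_pairs,
      " complete pairs)\n", sep = "")
  print(format(x$module_stats, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Select hub metabolites from trait-significant modules
#'
#' Metabolites of modules with trait p < `p_max` whose module membership
#' and metabolite significance exceed the thresholds strictly
#' (`MM > mm_min` and `MES > mes_min`), ordered by decreasing MM then id.
#'
#' @param stats a [module_trait_stats()] result.
#' @param mm_min module-membership threshold (default 0.7).
#' @param mes_min metabolite-significance threshold (default 0.15).
#' @param p_max module trait-correlation significance level (default
#'   0.05).
#' @return Character vector of hub metabolite ids (empty, with a warning,
#'   when no module is trait-significant).
#' @export
select_hub_metabolites <- function(stats, mm_min = 0.7, mes_min = 0.15,
                                   p_max = 0.05) {
  stopifnot(inherits(stats, "module_trait_stats"))
  sig <- stats$module_stats$module[stats$module_stats$p < p_max]
  if (!length(sig)) {
    warning("no trait-significant modules; empty hub list")
    return(character(0))
  }
  tab <- stats$metabolite_stats
  hubs <- tab[!is.na(tab$module) & tab$module %in% sig &
                !is.na(tab$MM) & tab$MM > mm_min & tab$MES > mes_min, ]
  hubs$id[order(-hubs$MM, hubs$id)]
}

#' Run the full weighted metabolite co-expression analysis
#'
#' Convenience wrapper chaining [metabolite_correlation()],
#' [soft_threshold_scan()], [adjacency_matrix()], [tom_matrix()],
#' [detect_modules()], [module_eigenmetabolites()],
#' [module_trait_stats()] and [select_hub_metabolites()].
#'
#' @param abundance positive metabolites x samples matrix.
#' @param trait named per-sample numeric trait (HER2 IHC score); samples
#'   with missing trait are dropped pairwise in the trait statistics.
#' @param powers,rsq_target soft-threshold scan settings.
#' @param power force a soft-thresholding power (skips the scan choice).
#' @param min_module_size,cut_quantile module detection settings.
#' @param mm_min,mes_min,p_max hub selection settings.
#' @param method trait correlation type.
#' @return A `wmcna_fit` list with all intermediate results and `hubs`.
#' @export
wmcna <- function(abundance, trait, powers = 1:20, rsq_target = 0.85,
                  power = NULL, min_module_size = 5, cut_quantile = 0.92,
                  mm_min = 0.7, mes_min = 0.15, p_max = 0.05,
                  method = "pearson") {
  z <- standardize_metabolome(abundance)
  r <- cor(t(z))
  scan <- soft_threshold_scan(r, powers = powers, rsq_target = rsq_target)
  beta <- power %||% scan$chosen_power
  if (is.na(beta)) {
    warning("no power reached the scale-free target; using the best fit")
    beta <- scan$fit$power[which.max(scan$fit$signed_rsq)]
  }
  tom <- tom_matrix(adjacency_matrix(r, beta))
  partition <- detect_modules(1 - tom, min_module_size = min_module_size,
                              cut_quantile = cut_quantile)
  if (length(partition$sizes) == 0) {
    warning("no modules detected; eigenmetabolite and trait statistics skipped")
    eigens <- NULL; stats <- NULL; hubs <- character(0)
  } else {
    eigens <- module_eigenmetabolites(z, partition)
    stats <- module_trait_stats(z, partition, eigens, trait, method = method)
    hubs <- select_hub_metabolites(stats, mm_min = mm_min, mes_min = mes_min,
                                   p_max = p_max)
  }
  structure(list(standardized = z, correlation = r, scan = scan,
                 power = beta, tom = tom, partition = partition,
                 eigens = eigens, stats = stats, hubs = hubs),
            class = "wmcna_fit")
}

#' @export
print.wmcna_fit <- function(x, ...) {
  cat("Weighted metabolite co-expression network analysis\n")
  cat("  metabolites:", nrow(x$standardized),
      " samples:", ncol(x$standardized), "\n")
  cat("  soft power:", x$power, "\n")
  cat("  modules:", length(x$partition$sizes),
      " unassigned:", x$partition$n_unassigned, "\n")
  if (!is.null(x$stats)) {
    sig <- sum(x$stats$module_stats$p < 0.05)
    cat("  trait-significant modules (p < 0.05):", sig, "\n")
  }
  cat("  hub metabolites:", length(x$hubs), "\n")
  invisible(x)
}
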