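## Differential-abundance screening of serum metabolites between tumour
## and healthy groups: empirical-Bayes moderated t on log2 intensities,
## Benjamini-Hochberg FDR, and strict fold-change filters.

#' Thresholds for the differential-metabolite screen
#'
#' Defaults follow the conventional serum-metabolome screen: FDR < 0.05
#' and raw-scale fold change > 1.2 (up) or < 5/6 (down), all strict.
#'
#' @param fdr_max,fc_up,fc_down thresholds; `0 < fc_down < 1 < fc_up`.
#' @return List of class `dem_thresholds`.
#' @export
dem_thresholds <- function(fdr_max = 0.05, fc_up = 1.2, fc_down = 5 / 6) {
  if (!(fc_down > 0 && fc_down < 1 && fc_up > 1))
    stop("need 0 < fc_down < 1 < fc_up")
  if (fdr_max <= 0 || fdr_max >= 1) stop("fdr_max must be in (0, 1)")
  structure(list(fdr_max = fdr_max, fc_up = fc_up, fc_down = fc_down),
            class = "dem_thresholds")
}

check_two_groups <- function(abundance, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2)
    stop("group must have exactly two levels")
  if (length(group) != ncol(abundance))
    stop("group must be aligned to the sample columns")
  group
}

#' Raw-scale fold change per metabolite
#'
#' Ratio of arithmetic group means on the raw intensity scale,
#' case over control.
#'
#' @param abundance positive metabolites x samples matrix.
#' @param group two-level factor over samples.
#' @param case,control level names of the numerator and denominator groups
#'   (default `"GC"` over `"healthy"`).
#' @return Named vector of fold changes.
#' @export
fold_change <- function(abundance, group, case = "GC", control = "healthy") {
  stop_if_not_numeric_matrix(abundance, "abundance")
  if (any(abundance <= 0)) stop("abundances must be strictly positive")
  group <- check_two_groups(abundance, group)
  if (!all(c(case, control) %in% levels(group)))
    stop("case/control levels not found in group")
  rowMeans(abundance[, group == case, drop = FALSE]) /
    rowMeans(abundance[, group == control, drop = FALSE])
}

#' Screen differentially abundant metabolites
#'
#' The test is an empirical-Bayes moderated t on log2-transformed
#' intensities with BH FDR across all metabolites jointly; the fold change
#' is computed on the raw scale (arithmetic group means). A metabolite is
#' called up if `fdr < fdr_max` and `fc > fc_up`, down if `fdr < fdr_max`
#' and `fc < fc_down` (all inequalities strict), otherwise `ns`.
#'
#' @param abundance positive metabolites x samples matrix.
#' @param group two-level factor over samples (>= 2 samples per level).
#' @param thresholds a [dem_thresholds()].
#' @param case,control numerator/denominator group levels.
#' @param engine `"moderated"` (default) or `"welch"` for a plain Welch t
#'   sensitivity check.
#' @return A data.frame of class `dem_table` with columns `id`, `fc`,
#'   `log2fc`, `p`, `fdr`, `direction`; attributes `n_total`, `n_up`,
#'   `n_down` and the thresholds used.
#' @export
screen_dems <- function(abundance, group, thresholds = dem_thresholds(),
                        case = "GC", control = "healthy",
                        engine = c("moderated", "welch")) {
  engine <- match.arg(engine)
  stopifnot(inherits(thresholds, "dem_thresholds"))
  group <- check_two_groups(abundance, group)
  fc <- fold_change(abundance, group, case = case, control = control)
  logm <- log2(abundance)
  ## reference = control so the fit's log2fc is case minus control
  labels <- factor(group, levels = c(control, case))
  if (engine == "moderated") {
    fit <- moderated_t_two_group(logm, labels)
    p <- fit$table$p
  } else {
    xc <- logm[, labels == control, drop = FALSE]
    xt <- logm[, labels == case, drop = FALSE]
    p <- welch_rowwise(xt, xc)
  }
  fdr <- benjamini_hochberg(p)
  direction <- rep("ns", nrow(abundance))
  direction[fdr < thresholds$fdr_max & fc > thresholds$fc_up] <- "up"
  direction[fdr < thresholds$fdr_max & fc < thresholds$fc_down] <- "down"
  out <- data.frame(id = rownames(abundance), fc = fc, log2fc = log2(fc),
                    p = p, fdr = fdr, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("dem_table", "data.frame"),
            n_total = nrow(out), n_up = sum(direction == "up"),
            n_down = sum(direction == "down"), thresholds = thresholds,
            engine = engine)
}

welch_rowwise <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  df[se2 == 0] <- n1 + n2 - 2
  2 * pt(-abs(t), df)
}

#' @export
print.dem_table <- function(x, ...) {
  cat("Differential metabolite screen:", attr(x, "n_total"),
      "metabolites;", attr(x, "n_up"), "up,", attr(x, "n_down"),
      "down (engine:", paste0(attr(x, "engine"), ")"), "\n")
  th <- attr(x, "thresholds")
  cat(sprintf("  criteria: FDR < %g and fold change > %g or < %g\n",
              th$fdr_max, th$fc_up, signif(th$fc_down, 4)))
  invisible(x)
}

#' Summary counts of a DEM screen
#' @param object a `dem_table`.
#' @param ... unused.
#' @return List with `n_total`, `n_up`, `n_down`.
#' @export
summary.dem_table <- function(object, ...) {
  list(n_total = attr(object, "n_total"), n_up = attr(object, "n_up"),
       n_down = attr(object, "n_down"))
}

#' @export
write_results.dem_table <- function(x, path, format = "tsv", ...) {
  if (format == "tsv") {
    out <- x[c("id", "log2fc", "fc", "p", "fdr", "direction")]
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], signif, digits = 6)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(summary(x), path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported (dem_table, ", format,
              "); supported: tsv, json")
  invisible(path)
}
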