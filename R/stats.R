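## Self-contained statistical primitives used by every pipeline stage:
## multiplicity correction, two- and k-group tests, empirical-Bayes moderated
## t, Kaplan-Meier and the k-group log-rank test. Established packages
## (stats, survival, limma) are used as independent oracles in the test
## suite, never as the implementation here.

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment: for sorted p-values, `q_(i) = min_{j >= i}
#' p_(j) * n / j`, clipped at 1, returned in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Vector of adjusted q-values, same length and order as `p`.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}

new_test_result <- function(statistic, df, p, method, extra = list()) {
  structure(c(list(statistic = statistic, df = df, p.value = p,
                   method = method), extra),
            class = "mbs_test")
}

#' @export
print.mbs_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", format(x$statistic, digits = 5),
      " df =", paste(format(x$df, digits = 5), collapse = ", "),
      " p =", format.pval(x$p.value, digits = 4), "\n")
  invisible(x)
}

#' Pearson chi-square test of independence for a 2x2 table
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @param yates apply the Yates continuity correction (default `FALSE`;
#'   cohort characteristic tables are conventionally reported uncorrected).
#' @return An object of class `mbs_test` with `statistic`, `df` (= 1) and
#'   `p.value`.
#' @examples
#' chi_square_independence(matrix(c(78, 89, 34, 23), 2))
#' @export
chi_square_independence <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("a 2x2 count table is required")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin")
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  dev <- abs(table - expected)
  if (yates) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / expected)
  new_test_result(stat, 1, pchisq(stat, 1, lower.tail = FALSE),
                  "Pearson chi-square test of independence (2x2)")
}

#' Two-sample t test from group summaries
#'
#' Two-sided t test computed from per-group mean, SD and size, as needed
#' to reproduce cohort-table comparisons when only summaries are printed.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @param pooled use the pooled-variance statistic with `n1 + n2 - 2` df
#'   (default); `FALSE` gives the Welch statistic.
#' @return An `mbs_test`.
#' @export
t_test_from_summary <- function(m1, s1, n1, m2, s2, n2, pooled = TRUE) {
  if (any(c(s1, s2) <= 0)) stop("standard deviations must be positive")
  if (any(c(n1, n2) < 2)) stop("each group needs n >= 2")
  if (pooled) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1
    v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  new_test_result(t, df, 2 * pt(-abs(t), df),
                  if (pooled) "Pooled two-sample t test (summaries)"
                  else "Welch two-sample t test (summaries)")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Mid-ranks are used for ties. The two-sided p-value is exact (complete
#' enumeration of rank assignments) when `length(x) + length(y) <= 16` and
#' there are no ties; otherwise a tie-corrected normal approximation is
#' used.
#'
#' @param x,y numeric samples, each with at least 2 observations.
#' @return An `mbs_test`; `statistic` is the rank sum W of `x`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  all_v <- c(x, y)
  if (length(unique(all_v)) == 1) {
    warning("all values identical across both groups; p = 1")
    return(new_test_result(n1 * (n + 1) / 2, NA_real_, 1,
                           "Wilcoxon rank-sum test (degenerate)"))
  }
  r <- rank(all_v)  # mid-ranks
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- any(duplicated(all_v))
  if (n <= 16 && !ties) {
    ## exact null: all C(n, n1) rank subsets equally likely
    sums <- combn(n, n1, FUN = sum)
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    return(new_test_result(w, NA_real_, p,
                           "Exact Wilcoxon rank-sum test"))
  }
  tie_tab <- table(all_v)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  z <- (w - mu) / sqrt(sigma2)
  new_test_result(w, NA_real_, 2 * pnorm(-abs(z)),
                  "Wilcoxon rank-sum test (normal approximation)",
                  extra = list(z = z))
}

#' Kruskal-Wallis rank test for k groups
#'
#' Tie-corrected H statistic referred to a chi-square distribution with
#' `k - 1` df.
#'
#' @param groups list of numeric vectors, one per group (k >= 2, each
#'   non-empty, total n >= 3).
#' @return An `mbs_test`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 1)) stop("every group needs >= 1 observation")
  values <- unlist(groups, use.names = FALSE)
  n <- length(values)
  if (n < 3) stop("need >= 3 observations in total")
  r <- rank(values)
  g <- rep(seq_along(groups), sizes)
  rsum <- tapply(r, g, sum)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / sizes) - 3 * (n + 1)
  tie_tab <- table(values)
  correction <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  if (correction == 0) {
    ## all observations identical: no evidence against the null
    h <- 0
  } else {
    h <- h / correction
  }
  df <- length(groups) - 1
  new_test_result(h, df, pchisq(h, df, lower.tail = FALSE),
                  "Kruskal-Wallis rank test (tie-corrected)")
}

## Newton solve of trigamma(y) = x, y > 0 (Smyth 2004, limma's iteration).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderated t for a two-group comparison
#'
#' Per-feature two-group comparison on log-scale data with residual
#' variances shrunk towards a common prior by empirical Bayes (Smyth 2004).
#' The prior df `d0` and prior variance `s0_sq` are estimated by method of
#' moments on the log sample variances; the posterior variance of feature g
#' is `(d0 * s0_sq + d_g * s_g^2) / (d0 + d_g)` and the moderated t has
#' `d0 + n1 + n2 - 2` df.
#'
#' @param log_matrix features x samples numeric matrix of log-scale values.
#' @param labels two-level factor (or vector) over samples; the first level
#'   is the reference, so `log2fc` is level2 minus level1 per feature.
#' @param d0 optionally force the prior df (0 recovers the ordinary pooled
#'   t; `Inf` pools a single common variance across features).
#' @return A `moderated_fit` list: `d0`, `s0_sq`, `df_total` and a
#'   data.frame `table` with `log2fc`, `s2` (pooled residual variance),
#'   `post_var`, `t`, `p` and a `zero_var` flag per feature.
#' @export
moderated_t_two_group <- function(log_matrix, labels, d0 = NULL) {
  stop_if_not_numeric_matrix(log_matrix, "log_matrix")
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  if (length(labels) != ncol(log_matrix))
    stop("labels must match the number of samples (columns)")
  n1 <- sum(labels == levels(labels)[1])
  n2 <- sum(labels == levels(labels)[2])
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")
  x1 <- log_matrix[, labels == levels(labels)[1], drop = FALSE]
  x2 <- log_matrix[, labels == levels(labels)[2], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  dg <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / dg
  zero_var <- s2 <= 0
  if (is.null(d0)) {
    hp <- fit_variance_prior(s2[!zero_var], dg)
    d0 <- hp$d0; s0_sq <- hp$s0_sq
  } else {
    s0_sq <- if (is.finite(d0) && d0 > 0) {
      fit_variance_prior(s2[!zero_var], dg)$s0_sq
    } else if (is.infinite(d0)) mean(s2) else mean(s2[!zero_var])
  }
  if (any(zero_var))
    warning(sum(zero_var), " zero-variance feature(s); shrunk to the prior")
  post_var <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + dg * s2) / (d0 + dg)
  lfc <- m2 - m1
  se <- sqrt(post_var * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, lfc / se, 0)
  ## cap the total df at the pooled residual df (the shrunk variance can
  ## never be better determined than the pooled estimate)
  df_total <- min(d0 + dg, dg * length(s2))
  p <- 2 * pt(-abs(t), df_total)
  out <- list(d0 = d0, s0_sq = s0_sq, df_total = df_total,
              n1 = n1, n2 = n2,
              table = data.frame(log2fc = lfc, s2 = s2,
                                 post_var = post_var, t = t, p = p,
                                 zero_var = zero_var,
                                 row.names = rownames(log_matrix)))
  class(out) <- "moderated_fit"
  out
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat("Empirical-Bayes moderated t fit\n")
  cat("  features:", nrow(x$table), "  groups:", x$n1, "vs", x$n2, "\n")
  cat("  prior df d0 =", format(x$d0, digits = 4),
      "  prior variance s0^2 =", format(x$s0_sq, digits = 4), "\n")
  invisible(x)
}

## Method-of-moments fit of the scaled inverse chi-square variance prior
## (Smyth 2004): moments of log s^2 around a scaled F distribution.
fit_variance_prior <- function(s2, dg) {
  if (!length(s2)) return(list(d0 = Inf, s0_sq = 1))
  ## guard exact zeros already removed; log needs positives
  z <- log(s2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(dg / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s0_sq <- mean(s2)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Kaplan-Meier product-limit survival curve
#'
#' Censorings tied with an event time are counted as still at risk at that
#' time (the standard convention).
#'
#' @param times non-negative follow-up times.
#' @param events event indicators in \{0, 1\} (1 = event, 0 = censored).
#' @return A `km_curve` list: `time` (distinct event times, increasing),
#'   `n_risk`, `n_event`, `survival` (step values), and `censor_times`.
#' @examples
#' km_curve(c(1, 2, 3), c(1, 0, 1))
#' @export
km_curve <- function(times, events) {
  if (!length(times)) stop("empty input")
  if (length(times) != length(events)) stop("times/events length mismatch")
  if (any(times < 0)) stop("times must be >= 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  et <- sort(unique(times[events == 1]))
  n_risk <- vapply(et, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = et, n_risk = n_risk, n_event = n_event,
                 survival = surv,
                 censor_times = sort(times[events == 0]),
                 n = length(times)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param curve a [km_curve()] object.
#' @param t times at which to evaluate S(t).
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(ti) {
    idx <- which(curve$time <= ti)
    if (!length(idx)) 1 else curve$survival[max(idx)]
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n, "subjects,",
      sum(x$n_event), "events at", length(x$time), "distinct times\n")
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "time", ylab = "survival", ...) {
  tt <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$survival, each = 2)[-(2 * length(x$survival))])
  plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  if (length(x$censor_times))
    points(x$censor_times, km_survival_at(x, x$censor_times), pch = 3)
  invisible(x)
}

#' k-group log-rank test
#'
#' Observed-minus-expected events aggregated over distinct event times with
#' the hypergeometric variance (simultaneous handling of tied events); the
#' chi-square statistic uses a generalized inverse of the covariance of the
#' first k - 1 groups and has k - 1 df.
#'
#' @param times,events as in [km_curve()].
#' @param group_labels group membership, k >= 2 levels, each non-empty.
#' @return An `mbs_test` with per-group observed and expected counts in
#'   `observed` / `expected`.
#' @export
logrank_test <- function(times, events, group_labels) {
  g <- as.factor(group_labels)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(tabulate(g, nlevels(g)) == 0)) stop("a group has no subjects")
  if (length(times) != length(g) || length(events) != length(g))
    stop("times, events and group_labels must have equal length")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  k <- nlevels(g)
  et <- sort(unique(times[events == 1]))
  O <- E <- setNames(numeric(k), levels(g))
  V <- matrix(0, k, k, dimnames = list(levels(g), levels(g)))
  for (t in et) {
    at_risk <- times >= t
    n <- sum(at_risk)
    d <- sum(times == t & events == 1)
    nj <- vapply(levels(g), function(l) sum(at_risk & g == l), numeric(1))
    dj <- vapply(levels(g), function(l)
      sum(times == t & events == 1 & g == l), numeric(1))
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      frac <- nj / n
      Vt <- d * (n - d) / (n - 1) * (diag(frac) - outer(frac, frac))
      V <- V + Vt
    }
  }
  idx <- seq_len(k - 1)
  dvec <- (O - E)[idx]
  stat <- drop(t(dvec) %*% pseudo_inverse(V[idx, idx, drop = FALSE]) %*% dvec)
  df <- k - 1
  new_test_result(stat, df, pchisq(stat, df, lower.tail = FALSE),
                  sprintf("%d-group log-rank test", k),
                  extra = list(observed = O, expected = E))
}
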