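## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Round half away from zero (Table-style rendering); base round() is
## round-half-even.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_if_not_numeric_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  invisible(x)
}

check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", what, ": ", paste(head(dup, 5), collapse = ", "),
         call. = FALSE)
  invisible(ids)
}

## z-score rows (features) of a features x samples matrix
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  (x - mu) / s
}

## Moore-Penrose pseudo-inverse via SVD (used for the k-group log-rank
## quadratic form; avoids a MASS dependency).
pseudo_inverse <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d, 0)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used to compare recovered subtypes or modules with planted truth.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return A number in (-1, 1]; 1 means identical partitions up to label
#'   permutation, 0 is the expected value under random labelings.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
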