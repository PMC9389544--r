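## Readers/writers for the delimited matrix, GMT, clinical-table, GraphML
## and JSON formats the pipeline touches, plus configuration handling and
## cohort summarisation.

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_com) "\t" else ","
}

#' Read a feature x sample matrix from a delimited text file
#'
#' The file must have a header row of sample ids and a first column of
#' feature ids; the delimiter (tab or comma) is auto-detected from the
#' header. Matrices are features x samples everywhere in this package.
#'
#' @param path file path.
#' @param kind `"expression"` (log2-scale values, any sign) or
#'   `"metabolome"` (strictly positive raw intensities).
#' @param missing policy for missing cells when `kind = "metabolome"`:
#'   `"reject"` (default) or `"min-impute"` (half the metabolite's observed
#'   minimum).
#' @return Numeric matrix with feature ids as rownames and sample ids as
#'   colnames; attribute `delimiter` records what was detected.
#' @export
read_matrix <- function(path, kind = c("expression", "metabolome"),
                        missing = c("reject", "min-impute")) {
  kind <- match.arg(kind)
  missing <- match.arg(missing)
  delim <- detect_delim(path)
  df <- read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected a feature-id column plus >= 1 sample")
  ids <- as.character(df[[1]])
  check_unique_ids(ids, "feature id")
  check_unique_ids(colnames(df)[-1], "sample id")
  vals <- df[-1]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA" & v != "")
      if (length(bad))
        stop(sprintf("non-numeric cell at row '%s', sample '%s': '%s'",
                     ids[bad[1]], colnames(vals)[j], v[bad[1]]))
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (anyNA(m)) {
    if (kind == "metabolome" && missing == "min-impute") {
      for (i in which(rowSums(is.na(m)) > 0)) {
        mn <- min(m[i, ], na.rm = TRUE)
        m[i, is.na(m[i, ])] <- mn / 2
      }
    } else {
      miss <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("missing value at feature '%s', sample '%s'",
                   rownames(m)[miss[1]], colnames(m)[miss[2]]))
    }
  }
  if (kind == "metabolome" && any(m <= 0)) {
    bad <- which(m <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive intensity at metabolite '%s', sample '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  attr(m, "delimiter") <- if (delim == "\t") "tab" else "comma"
  m
}

#' Write a feature x sample matrix as TSV at full precision
#'
#' @param m numeric matrix with rownames (feature ids) and colnames.
#' @param path output path.
#' @param id_column header for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_column = "feature_id") {
  stop_if_not_numeric_matrix(m)
  df <- data.frame(id = rownames(m),
                   ## full-precision rendering so a write/read round-trip
                   ## is bitwise exact
                   apply(m, 2, function(col) sprintf("%.17g", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table (CSV/TSV)
#'
#' Expected columns: `sample_id`, `group`, and optionally `os_time`,
#' `os_event`, `dss_time`, `dss_event`, `stage`, `grade`, `her2_ihc`
#' (ordinal 0-3) and `immune_subtype` (C1-C6). Invariants (times >= 0,
#' events in \{0, 1\}, HER2 IHC in 0..3) are enforced on load.
#'
#' @param path file path.
#' @return A data.frame with one row per sample.
#' @export
read_clinical <- function(path) {
  delim <- detect_delim(path)
  df <- read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(df)))
    stop("clinical table needs 'sample_id' and 'group' columns")
  check_unique_ids(df$sample_id, "sample id")
  validate_clinical(df)
  df
}

validate_clinical <- function(df) {
  for (col in intersect(c("os_time", "dss_time"), colnames(df))) {
    v <- df[[col]]
    if (any(v < 0, na.rm = TRUE)) stop(col, " must be >= 0")
  }
  for (col in intersect(c("os_event", "dss_event"), colnames(df))) {
    v <- df[[col]]
    if (!all(v %in% c(0, 1, NA))) stop(col, " must be 0 or 1")
  }
  if ("her2_ihc" %in% colnames(df) &&
      !all(df$her2_ihc %in% c(0:3, NA)))
    stop("her2_ihc must be in 0..3 where present")
  invisible(df)
}

#' Read a GMT gene-set file
#'
#' Standard dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a set are dropped with a warning.
#'
#' @param path file path.
#' @return Named list of character vectors of member ids; descriptions are
#'   kept in attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 member",
                   i, length(fields)))
    name <- fields[1]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("set '%s': duplicate members de-duplicated", name))
      members <- unique(members)
    }
    if (!length(members)) stop(sprintf("GMT line %d: empty set '%s'", i, name))
    if (name %in% names(sets)) stop("duplicate set name: ", name)
    sets[[name]] <- members
    descs[name] <- fields[2]
  }
  if (!length(sets)) stop("no gene sets found in ", path)
  attr(sets, "descriptions") <- descs
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a pipeline result to disk
#'
#' Generic writer with a deterministic field order; floats in tabular
#' results are rendered with 6 significant digits (matrices keep full
#' precision via [write_matrix()]). Networks are written as GraphML.
#'
#' @param x a result object (`dem_table`, `mmi_network`, `subtype_scores`,
#'   a named list, or a matrix).
#' @param path output path.
#' @param format `"tsv"`, `"json"` or `"graphml"`; the supported pairs are
#'   documented per method.
#' @param ... passed on to methods.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format, ...) UseMethod("write_results")

#' @export
write_results.default <- function(x, path, format = "json", ...) {
  if (format != "json")
    stop("unsupported (object, format) pair; supported: (list, json)")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
write_results.matrix <- function(x, path, format = "tsv", ...) {
  if (format != "tsv")
    stop("unsupported (object, format) pair; supported: (matrix, tsv)")
  write_matrix(x, path, ...)
}

#' @export
write_results.data.frame <- function(x, path, format = "tsv", ...) {
  if (format != "tsv")
    stop("unsupported (object, format) pair; supported: (data.frame, tsv)")
  out <- x
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarise a cohort the way clinical characteristic tables are printed
#'
#' Per categorical variable and level: count `n` and percentage
#' `100 * n / N` rounded half-up to one decimal, where `N` is the full
#' cohort size of the arm (missing values are shown as an `NA` level, so
#' percentages of a complete variable sum to 100).
#'
#' @param clinical clinical data.frame (see [read_clinical()]).
#' @param variables character vector of categorical column names.
#' @return A data.frame with `variable`, `level`, `n`, `pct` and a
#'   `formatted` column like `"78 (69.6%)"`.
#' @export
summarize_cohort <- function(clinical, variables) {
  unknown <- setdiff(variables, colnames(clinical))
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  N <- nrow(clinical)
  rows <- lapply(variables, function(v) {
    x <- clinical[[v]]
    x <- ifelse(is.na(x), "NA", as.character(x))
    tab <- table(x)
    pct <- round_half_up(100 * as.numeric(tab) / N, 1)
    data.frame(variable = v, level = names(tab), n = as.numeric(tab),
               pct = pct,
               formatted = sprintf("%d (%.1f%%)", as.numeric(tab), pct),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default analysis configuration
#'
#' All tunable thresholds of the downstream modules with their defaults:
#' DEM screen (FDR 0.05, fold change > 1.2 or < 5/6), WMCNA (scale-free
#' R-squared target 0.85, powers 1..20, minimum module size 5, static cut
#' fraction 0.92, hub criteria MM > 0.7 and MES > 0.15), MMI (|r| > 0.4),
#' consensus clustering (k = 3, 100 resampling reps, 80% item sampling,
#' all features) and ssGSEA (rank-weight exponent 0.25).
#'
#' @param ... named overrides of any default (nested lists are merged).
#' @return A validated nested list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    dem = list(fdr_max = 0.05, fc_up = 1.2, fc_down = 5 / 6),
    wmcna = list(rsq_target = 0.85, powers = 1:20, min_module_size = 5,
                 cut_quantile = 0.92, mm_min = 0.7, mes_min = 0.15),
    mmi = list(r_threshold = 0.4),
    consensus = list(k = 3, reps = 100, p_item = 0.8, p_feature = 1.0),
    ssgsea = list(alpha = 0.25, normalize = TRUE),
    seed = 1L
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else cfg[[nm]] <- overrides[[nm]]
  }
  validate_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$dem$fdr_max > 0, cfg$dem$fdr_max < 1,
    cfg$dem$fc_down > 0, cfg$dem$fc_down < 1, cfg$dem$fc_up > 1,
    cfg$wmcna$rsq_target > 0, cfg$wmcna$rsq_target <= 1,
    cfg$wmcna$cut_quantile > 0, cfg$wmcna$cut_quantile <= 1,
    cfg$mmi$r_threshold >= 0, cfg$mmi$r_threshold < 1,
    cfg$consensus$k >= 2, cfg$consensus$reps >= 1,
    cfg$consensus$p_item > 0, cfg$consensus$p_item <= 1,
    cfg$consensus$p_feature > 0, cfg$consensus$p_feature <= 1,
    cfg$ssgsea$alpha >= 0
  )
  invisible(cfg)
}

#' Read an analysis configuration from YAML or JSON
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return An `analysis_config` with file values layered over the defaults.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, vals)
}
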