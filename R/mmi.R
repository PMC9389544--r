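## Metabolite-metabolite interaction network: correlation-thresholded
## edges among selected (hub) metabolites, degree summaries, GraphML
## export.

#' Build a metabolite-metabolite interaction network
#'
#' Pairwise Pearson correlations on the log2-standardized scale (the same
#' scale as the co-expression network); an edge is kept where
#' `|r| > r_threshold` strictly. Isolated nodes are retained.
#'
#' @param abundance positive metabolites x samples matrix (>= 4 samples).
#' @param metabolites optional character vector restricting the network to
#'   selected (e.g. hub) metabolites; default all.
#' @param r_threshold edge threshold on `|r|` (default 0.4).
#' @param log2 passed to [standardize_metabolome()].
#' @return An `mmi_network`: `nodes`, `edges` (data.frame `from`, `to`,
#'   `r` with from < to), `degree`, `r_threshold`.
#' @export
build_mmi_network <- function(abundance, metabolites = NULL,
                              r_threshold = 0.4, log2 = TRUE) {
  if (!is.null(metabolites)) {
    missing_ids <- setdiff(metabolites, rownames(abundance))
    if (length(missing_ids))
      stop("metabolites absent from the matrix: ",
           paste(head(missing_ids, 5), collapse = ", "))
    abundance <- abundance[metabolites, , drop = FALSE]
  }
  if (nrow(abundance) < 2) stop("need >= 2 metabolites")
  r <- metabolite_correlation(abundance, log2 = log2)
  nodes <- rownames(r)
  pairs <- which(upper.tri(r) & abs(r) > r_threshold, arr.ind = TRUE)
  edges <- data.frame(from = nodes[pairs[, 1]], to = nodes[pairs[, 2]],
                      r = r[pairs], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  degree <- setNames(tabulate(match(c(edges$from, edges$to), nodes),
                              nbins = length(nodes)), nodes)
  structure(list(nodes = nodes, edges = edges, degree = degree,
                 r_threshold = r_threshold),
            class = "mmi_network")
}

#' Summary counts and degree statistics of an MMI network
#'
#' @param net an [build_mmi_network()] result.
#' @return List with `n_nodes`, `n_edges`, `degree_min`, `degree_median`,
#'   `degree_max`, `n_isolated`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "mmi_network"))
  list(n_nodes = length(net$nodes),
       n_edges = nrow(net$edges),
       degree_min = min(net$degree),
       degree_median = median(net$degree),
       degree_max = max(net$degree),
       n_isolated = sum(net$degree == 0))
}

#' @export
print.mmi_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("MMI network (|r| > %g): %d nodes, %d edges, %d isolated\n",
              x$r_threshold, s$n_nodes, s$n_edges, s$n_isolated))
  invisible(x)
}

#' Convert an MMI network to an igraph object
#' @param net an `mmi_network`.
#' @return An undirected `igraph` graph with edge attribute `weight` (the
#'   correlation, 6 significant digits) including isolated nodes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "mmi_network"))
  g <- igraph::graph_from_data_frame(
    transform(net$edges, weight = signif(r, 6)),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
  g
}

#' @export
write_results.mmi_network <- function(x, path, format = "graphml", ...) {
  if (format == "graphml") {
    igraph::write_graph(as_igraph(x), path, format = "graphml")
  } else if (format == "tsv") {
    out <- x$edges
    out$r <- signif(out$r, 6)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop("unsupported (mmi_network, ", format,
              "); supported: graphml, tsv")
  invisible(path)
}
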