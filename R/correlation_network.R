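#' Co-regulation network of significant correlation edges
#'
#' An undirected graph over protein features. Each edge records the Pearson
#' correlation `r`, its raw and BH-adjusted p-value, and the sign
#' (`positive` iff r > 0). Edges are stored once under the canonical
#' (lexicographic) ordering of the pair; self-loops and duplicate pairs are
#' rejected.
#'
#' @param edges data.frame with columns `protein_a`, `protein_b`, `r`,
#'   `p_raw`, `p_adj`, `sign`.
#' @param nodes character vector of node IDs; defaults to the union of edge
#'   endpoints. Nodes with no edges are allowed (they count in the
#'   all-possible-pairs denominators).
#' @param r_min,alpha thresholds the network was built with (provenance).
#' @param n_samples number of samples the correlations were computed over.
#' @return object of class `correlation_network`.
#' @export
correlation_network <- function(edges, nodes = NULL, r_min = 0.95, alpha = 0.01,
                                n_samples = NA_integer_) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  req <- c("protein_a", "protein_b", "r", "p_raw", "p_adj", "sign")
  if (!all(req %in% names(edges))) {
    stopf("edges must have columns: %s", paste(req, collapse = ", "))
  }
  if (nrow(edges)) {
    if (any(edges$protein_a == edges$protein_b)) stopf("self-loop edges are not allowed")
    if (any(abs(edges$r) > 1 | is.na(edges$r))) stopf("edge r outside [-1, 1]")
    cp <- canonical_pairs(edges$protein_a, edges$protein_b)
    edges$protein_a <- cp$a
    edges$protein_b <- cp$b
    if (anyDuplicated(paste(edges$protein_a, edges$protein_b, sep = "\r"))) {
      stopf("duplicate unordered pairs in edge list")
    }
    edges$sign <- ifelse(edges$r > 0, "positive", "negative")
    edges <- edges[order(edges$protein_a, edges$protein_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- sort(unique(c(nodes, edges$protein_a, edges$protein_b)))
  structure(list(edges = edges, nodes = nodes, r_min = r_min, alpha = alpha,
                 n_samples = n_samples),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("correlation_network: %d nodes, %d edges (%.1f%% positive)\n",
              s$n_nodes, s$n_edges, s$pct_positive))
  cat(sprintf("thresholds: |r| >= %.3g, BH p < %.3g\n", x$r_min, x$alpha))
  invisible(x)
}

#' Summary counts for a correlation network
#'
#' @param net [correlation_network()]
#' @return list with `n_nodes`, `n_edges`, `n_positive`, `n_negative`,
#'   `pct_positive` (percentage of edges with r > 0).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "correlation_network"))
  npos <- sum(net$edges$sign == "positive")
  ne <- nrow(net$edges)
  list(n_nodes = length(net$nodes), n_edges = ne, n_positive = npos,
       n_negative = ne - npos,
       pct_positive = if (ne) 100 * npos / ne else NA_real_)
}

#' Write / read a network edge list as TSV
#'
#' Columns `protein_a`, `protein_b`, `r`, `p_raw`, `p_adj`, `sign`;
#' `read_edge_list()` is the exact inverse and validates every row (r within
#' \eqn{[-1, 1]}, p-values in (0, 1], no self-loops), reporting the offending
#' line number on failure.
#'
#' @param net [correlation_network()]
#' @param path TSV path.
#' @rdname edge_list_io
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "correlation_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param r_min,alpha,n_samples provenance fields to attach on read.
#' @rdname edge_list_io
#' @export
read_edge_list <- function(path, r_min = 0.95, alpha = 0.01, n_samples = NA_integer_) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("protein_a", "protein_b", "r", "p_raw", "p_adj", "sign")
  if (!all(req %in% names(tab))) stopf("edge list %s lacks required columns", path)
  bad <- which(is.na(tab$r) | abs(tab$r) > 1 |
                 is.na(tab$p_raw) | tab$p_raw <= 0 | tab$p_raw > 1 |
                 is.na(tab$p_adj) | tab$p_adj <= 0 | tab$p_adj > 1 |
                 tab$protein_a == tab$protein_b)
  if (length(bad)) {
    # +1 for the header row so the number matches the file
    stopf("malformed edge row(s) at line(s): %s",
          paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  correlation_network(tab, r_min = r_min, alpha = alpha, n_samples = n_samples)
}

#' Per-node degree and summary statistics
#'
#' Degrees are counted over the retained (significant) edges. An empty
#' network yields zeros with a warning.
#'
#' @param net [correlation_network()]
#' @return list with `mean_degree`, `sd_degree`, and `degrees` (data.frame
#'   node/degree over all network nodes, including isolated ones).
#' @export
degree_stats <- function(net) {
  stopifnot(inherits(net, "correlation_network"))
  if (!nrow(net$edges)) {
    warnf("network has no edges; degree statistics are zero")
    deg <- data.frame(node = net$nodes, degree = integer(length(net$nodes)))
    return(list(mean_degree = 0, sd_degree = 0, degrees = deg))
  }
  counts <- table(factor(c(net$edges$protein_a, net$edges$protein_b),
                         levels = net$nodes))
  deg <- data.frame(node = net$nodes, degree = as.integer(counts),
                    stringsAsFactors = FALSE)
  list(mean_degree = mean(deg$degree), sd_degree = stats::sd(deg$degree),
       degrees = deg)
}
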