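#' Differentially abundant features between two stages
#'
#' Per feature: the log2 fold change between the two stages' mean abundances
#' (mean difference on the log2 scale for `log2_ratio` matrices, log2 of the
#' ratio of means for `raw` matrices) and a two-sided two-sample t-test
#' across replicates, BH-adjusted over all tested features. A feature is
#' flagged differentially abundant iff `|FC| > log2(fc_threshold)` and
#' `p_adj < alpha`.
#'
#' @param am [abundance_matrix()]
#' @param stage_a,stage_b stage labels; fold change is b over a.
#' @param fc_threshold linear fold-change threshold (default 2).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param var_equal use the pooled-variance Student's t (default `TRUE`);
#'   `FALSE` gives Welch.
#' @param group optional sample-sheet filter, e.g. `cell_line = "lineA"`,
#'   given as a named list.
#' @return data.frame with `feature`, `log2_fc`, `p_raw`, `p_adj`, `is_dap`.
#' @export
compute_daps <- function(am, stage_a, stage_b, fc_threshold = 2, alpha = 0.05,
                         var_equal = TRUE, group = NULL) {
  stopifnot(inherits(am, "abundance_matrix"))
  keep <- rep(TRUE, nrow(am$samples))
  for (nm in names(group)) keep <- keep & am$samples[[nm]] %in% group[[nm]]
  st <- as.character(am$samples$stage)
  ia <- which(keep & st == stage_a)
  ib <- which(keep & st == stage_b)
  if (length(ia) < 2) stopf("stage %s has fewer than 2 replicates", stage_a)
  if (length(ib) < 2) stopf("stage %s has fewer than 2 replicates", stage_b)
  va <- am$values[, ia, drop = FALSE]
  vb <- am$values[, ib, drop = FALSE]
  if (am$scale == "raw") {
    lfc <- log2(rowMeans(vb, na.rm = TRUE) / rowMeans(va, na.rm = TRUE))
    va <- log2(va); vb <- log2(vb)  # test on the log scale
  } else {
    lfc <- rowMeans(vb, na.rm = TRUE) - rowMeans(va, na.rm = TRUE)
  }
  p <- vapply(seq_len(nrow(va)), function(i) {
    x <- va[i, ]; y <- vb[i, ]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    if (stats::sd(c(x, y)) == 0) return(1)
    stats::t.test(y, x, var.equal = var_equal)$p.value
  }, numeric(1))
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(feature = rownames(am$values), log2_fc = lfc, p_raw = p,
             p_adj = padj,
             is_dap = !is.na(padj) & abs(lfc) > log2(fc_threshold) & padj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Temporal clustering of per-feature stage profiles
#'
#' Features are summarized to per-stage means, z-scored per feature, and
#' clustered hierarchically on correlation distance (`1 - r`) with average
#' linkage (both configurable), then cut into `k` clusters. Deterministic
#' given the input; the unordered partition is invariant to feature-row
#' permutation.
#'
#' @param am [abundance_matrix()] (complete over the clustered samples).
#' @param k number of clusters (default 10).
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage linkage method for [stats::hclust()] (default `"average"`).
#' @return named integer vector of cluster assignments (renumbered so that
#'   cluster labels follow each cluster's first feature in the input order).
#' @export
cluster_temporal <- function(am, k = 10, distance = c("correlation", "euclidean"),
                             linkage = "average") {
  stopifnot(inherits(am, "abundance_matrix"))
  distance <- match.arg(distance)
  if (k > nrow(am$values)) stopf("k = %d exceeds feature count %d", k, nrow(am$values))
  prof <- stage_means(am)
  z <- t(scale(t(prof)))
  z[!is.finite(z)] <- 0  # constant profiles carry no shape information
  d <- if (distance == "correlation") {
    stats::as.dist(1 - stats::cor(t(z)))
  } else {
    stats::dist(z)
  }
  hc <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(hc, k = k)
  # relabel by order of first appearance so the partition, not the dendrogram
  # orientation, defines the labels
  stats::setNames(match(cl, unique(cl)), rownames(prof))
}

# per-feature mean over samples of each stage (columns ordered by stage level)
stage_means <- function(am, group = NULL) {
  keep <- rep(TRUE, nrow(am$samples))
  for (nm in names(group)) keep <- keep & am$samples[[nm]] %in% group[[nm]]
  st <- am$samples$stage
  lev <- if (is.factor(st)) levels(st) else unique(as.character(st))
  lev <- lev[lev %in% as.character(st[keep])]
  out <- vapply(lev, function(s) {
    rowMeans(am$values[, keep & as.character(st) == s, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(am$values)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(am$values), lev))
  out
}

# per-feature mean over each group x stage condition
condition_means <- function(am, condition_by = c("cell_line", "stage")) {
  fac <- interaction(am$samples[condition_by], drop = TRUE, sep = ".")
  out <- vapply(levels(fac), function(lv) {
    rowMeans(am$values[, fac == lv, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(am$values)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(am$values), levels(fac)))
  out
}

#' One-sided hypergeometric (over-representation) enrichment
#'
#' For each gene set, the upper-tail probability `P(X >= overlap)` of the
#' observed overlap between the selection and the set under sampling without
#' replacement from the background universe, BH-adjusted across tested sets.
#' Set membership is intersected with the background first.
#'
#' @param selected character vector of selected features (must be a subset of
#'   `background`).
#' @param background character vector, the universe.
#' @param gsc [gene_set_collection()]
#' @return data.frame with `set`, `source`, `set_size` (in universe),
#'   `overlap`, `p_raw`, `p_adj`.
#' @export
hypergeometric_enrichment <- function(selected, background, gsc) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  selected <- unique(selected); background <- unique(background)
  if (!all(selected %in% background)) stopf("selected features must be a subset of the background")
  N <- length(background); n <- length(selected)
  res <- lapply(names(gsc$sets), function(nm) {
    members <- intersect(gsc$sets[[nm]], background)
    K <- length(members)
    ov <- length(intersect(members, selected))
    p <- if (K == 0) 1 else stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, source = unname(gsc$source[[nm]]), set_size = K,
               overlap = ov, p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out[order(out$p_adj, out$p_raw), , drop = FALSE]
}
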