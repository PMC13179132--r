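#' Normalize raw abundances to the per-feature geometric mean
#'
#' For each feature and each sample group (by default one group per species),
#' every value is divided by that feature's geometric mean over the group's
#' samples and log2-transformed, giving log2 ratios with per-feature,
#' per-group mean zero. This is the ratio normalization applied before all
#' correlation and fold-change analyses. Zeros and negative raw values are
#' treated as missing (non-detection) before the geometric mean; a feature
#' with no usable value in a group is reported missing across that group with
#' a warning. Applying the function to an already-normalized matrix is a hard
#' error (scale-tag guard).
#'
#' @param am raw-scale [abundance_matrix()]
#' @param group_by sample-sheet column(s) partitioning the samples (default
#'   `"species"`); `NULL` treats all samples as one group.
#' @return `abundance_matrix` with scale `"log2_ratio"`.
#' @export
normalize_to_geometric_mean <- function(am, group_by = "species") {
  stopifnot(inherits(am, "abundance_matrix"))
  if (am$scale != "raw") {
    stopf("matrix is already on %s scale; normalization expects raw values", am$scale)
  }
  vals <- am$values
  vals[!is.na(vals) & vals <= 0] <- NA_real_
  if (is.null(group_by)) {
    grp <- factor(rep("all", ncol(vals)))
  } else {
    missing_cols <- setdiff(group_by, names(am$samples))
    if (length(missing_cols)) stopf("sample sheet lacks column(s): %s",
                                    paste(missing_cols, collapse = ", "))
    grp <- interaction(am$samples[group_by], drop = TRUE)
  }
  out <- vals
  for (g in levels(grp)) {
    idx <- which(grp == g)
    sub <- log2(vals[, idx, drop = FALSE])
    gm <- rowMeans(sub, na.rm = TRUE)  # log2 of the geometric mean
    dead <- !is.finite(gm)
    if (any(dead)) {
      warnf("%d feature(s) with no usable value in group %s", sum(dead), g)
      gm[dead] <- NA_real_
    }
    out[, idx] <- sub - gm
  }
  if (inherits(am, "phosphosite_matrix")) {
    phosphosite_matrix(out, am$sites, am$samples, scale = "log2_ratio")
  } else {
    abundance_matrix(out, am$samples, scale = "log2_ratio")
  }
}

#' Merge two species' normalized matrices by orthology
#'
#' Restricts both matrices to ortholog pairs present in each, relabels the
#' second species' features by their orthologs' IDs, and binds the sample
#' columns. Features with any missing value across the retained samples are
#' dropped (complete-case), matching a correlation analysis that needs full
#' vectors.
#'
#' @param human,mouse log2-ratio [abundance_matrix()] objects.
#' @param map data.frame with columns `human`, `mouse` (one-to-one).
#' @return merged `abundance_matrix` keyed by the human feature IDs.
#' @export
merge_by_orthology <- function(human, mouse, map) {
  stopifnot(inherits(human, "abundance_matrix"), inherits(mouse, "abundance_matrix"))
  if (human$scale != "log2_ratio" || mouse$scale != "log2_ratio") {
    stopf("both matrices must be normalized (log2_ratio) before merging")
  }
  validate_orthology_map(map)
  keep <- map$human %in% rownames(human$values) & map$mouse %in% rownames(mouse$values)
  map <- map[keep, , drop = FALSE]
  hv <- human$values[map$human, , drop = FALSE]
  mv <- mouse$values[map$mouse, , drop = FALSE]
  rownames(mv) <- map$human
  vals <- cbind(hv, mv)
  complete <- rowSums(is.na(vals)) == 0
  vals <- vals[complete, , drop = FALSE]
  common <- intersect(names(human$samples), names(mouse$samples))
  samples <- rbind(human$samples[, common, drop = FALSE],
                   mouse$samples[, common, drop = FALSE])
  abundance_matrix(vals, samples, scale = "log2_ratio")
}

#' Trim features (or a network) to canonical isoforms
#'
#' Retains only features whose accession carries no isoform suffix (a
#' trailing `-<integer>` after the accession body). For a network, edges
#' touching removed nodes are removed and the node set updated.
#'
#' @param x character vector of feature IDs, an [abundance_matrix()], or a
#'   [correlation_network()].
#' @return object of the same type, restricted to canonical features.
#' @export
trim_to_canonical <- function(x) {
  is_canonical <- function(ids) !grepl("-[0-9]+$", ids)
  if (is.character(x)) return(x[is_canonical(x)])
  if (inherits(x, "abundance_matrix")) {
    keep <- is_canonical(rownames(x$values))
    return(abundance_matrix(x$values[keep, , drop = FALSE], x$samples, scale = x$scale))
  }
  if (inherits(x, "correlation_network")) {
    nodes <- x$nodes[is_canonical(x$nodes)]
    e <- x$edges
    e <- e[e$protein_a %in% nodes & e$protein_b %in% nodes, , drop = FALSE]
    return(correlation_network(e, nodes = nodes, r_min = x$r_min,
                               alpha = x$alpha, n_samples = x$n_samples))
  }
  stopf("trim_to_canonical does not handle class %s", paste(class(x), collapse = "/"))
}

#' Convert a count matrix to transcripts per million
#'
#' Adds a pseudocount, divides by gene length (if provided) and rescales each
#' sample to one million. With `gene_lengths = NULL` all genes are treated as
#' equal length (counts-per-million up to the pseudocount).
#'
#' @param am raw-scale [abundance_matrix()] of counts.
#' @param gene_lengths optional named numeric vector of lengths per feature.
#' @param pseudocount added to every count before scaling (default 1).
#' @return raw-scale `abundance_matrix` of TPM values.
#' @export
counts_to_tpm <- function(am, gene_lengths = NULL, pseudocount = 1) {
  stopifnot(inherits(am, "abundance_matrix"))
  if (am$scale != "raw") stopf("counts_to_tpm expects a raw-scale matrix")
  v <- am$values + pseudocount
  if (!is.null(gene_lengths)) {
    len <- gene_lengths[rownames(v)]
    if (any(is.na(len))) stopf("gene_lengths missing for some features")
    v <- v / len
  }
  tpm <- sweep(v, 2, colSums(v, na.rm = TRUE), "/") * 1e6
  abundance_matrix(tpm, am$samples, scale = "raw")
}
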