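#' Number of unordered feature pairs
#'
#' The size of the all-pairs correlation universe for `n` features (or a
#' feature vector): `n (n - 1) / 2`.
#'
#' @param features integer count or character vector of feature IDs.
#' @return numeric pair count (exact for any realistic n).
#' @export
count_feature_pairs <- function(features) {
  n <- if (is.numeric(features) && length(features) == 1) features else length(features)
  n * (n - 1) / 2
}

#' All-pairs Pearson correlations, computed in blocks
#'
#' Computes the Pearson correlation and its two-sided parametric p-value
#' (t transform with `n - 2` degrees of freedom) for every unordered feature
#' pair, processing the feature dimension in blocks so peak memory is
#' O(block^2 + features x samples) besides the returned (or streamed)
#' results. Pairs where either feature has zero variance get `r = NA` and
#' are excluded by downstream filtering.
#'
#' @param am [abundance_matrix()] complete over its samples; >= 3 samples.
#' @param block_size features per block (default 512).
#' @param FUN optional callback `function(df)` called with each block's
#'   data.frame of pairs instead of accumulating them; when supplied the
#'   function returns (invisibly) the total pair count only.
#' @return data.frame with `protein_a`, `protein_b` (canonically ordered),
#'   `r`, `p_raw` — or the pair count when `FUN` is given.
#' @export
pairwise_correlations <- function(am, block_size = 512, FUN = NULL) {
  stopifnot(inherits(am, "abundance_matrix"))
  v <- am$values
  ns <- ncol(v)
  if (ns < 3) stopf("need at least 3 samples for correlations (have %d)", ns)
  if (anyNA(v)) stopf("matrix must be complete over the sample axis")
  ids <- rownames(v)
  # row-standardize once: r is then a plain cross-product
  ctr <- v - rowMeans(v)
  ss <- sqrt(rowSums(ctr^2))
  zero_var <- ss == 0
  ss[zero_var] <- 1
  z <- ctr / ss
  nblocks <- ceiling(nrow(v) / block_size)
  starts <- (seq_len(nblocks) - 1) * block_size + 1
  acc <- if (is.null(FUN)) vector("list", nblocks * (nblocks + 1) / 2)
  k <- 0; total <- 0
  for (bi in seq_len(nblocks)) {
    ri <- starts[bi]:min(starts[bi] + block_size - 1, nrow(v))
    for (bj in bi:nblocks) {
      rj <- starts[bj]:min(starts[bj] + block_size - 1, nrow(v))
      rr <- tcrossprod(z[ri, , drop = FALSE], z[rj, , drop = FALSE])
      rr <- pmin(pmax(rr, -1), 1)
      if (bi == bj) {
        sel <- which(upper.tri(rr), arr.ind = TRUE)
      } else {
        sel <- as.matrix(expand.grid(row = seq_along(ri), col = seq_along(rj)))
      }
      a <- ids[ri[sel[, 1]]]; b <- ids[rj[sel[, 2]]]
      r <- rr[sel]
      r[zero_var[ri[sel[, 1]]] | zero_var[rj[sel[, 2]]]] <- NA_real_
      cp <- canonical_pairs(a, b)
      df <- data.frame(protein_a = cp$a, protein_b = cp$b, r = r,
                       p_raw = cor_pvalue(r, ns), stringsAsFactors = FALSE)
      total <- total + nrow(df)
      if (is.null(FUN)) {
        k <- k + 1
        acc[[k]] <- df
      } else {
        FUN(df)
      }
    }
  }
  if (is.null(FUN)) {
    out <- do.call(rbind, acc[seq_len(k)])
    rownames(out) <- NULL
    out
  } else invisible(total)
}

#' Permutation null distribution of pairwise correlations
#'
#' For each of `n_shuffles` rounds, every feature's sample vector is
#' independently permuted (destroying all co-regulation while preserving
#' per-feature marginals), `n_pairs` random feature pairs are drawn, and
#' their Pearson correlations collected. Pairs with zero variance on either
#' side are dropped. Reproducible from `seed`.
#'
#' @param am [abundance_matrix()], complete, >= 3 samples.
#' @param n_pairs pairs sampled per shuffle round (default 50000; capped with
#'   a warning at the number of available pairs).
#' @param n_shuffles shuffle rounds (default 10).
#' @param seed integer RNG seed.
#' @return object of class `null_distribution`: list with `r` (numeric
#'   vector), `n_pairs`, `n_shuffles`, `n_dropped`, `seed`.
#' @export
permutation_null <- function(am, n_pairs = 50000, n_shuffles = 10, seed = 1L) {
  stopifnot(inherits(am, "abundance_matrix"))
  v <- am$values
  if (ncol(v) < 3) stopf("need at least 3 samples")
  if (anyNA(v)) stopf("matrix must be complete")
  n <- nrow(v)
  avail <- count_feature_pairs(n)
  if (n_pairs > avail) {
    warnf("n_pairs capped at the %d available pairs", avail)
    n_pairs <- avail
  }
  set.seed(seed)
  draws <- vector("list", n_shuffles)
  for (s in seq_len(n_shuffles)) {
    perm <- t(apply(v, 1, sample))
    # n_pairs distinct unordered pairs per round: draw linear indices into
    # the upper triangle (row-major) and decode
    k <- sample(avail, n_pairs)
    i <- ceiling(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * k)) / 2)
    j <- k - ((i - 1) * n - (i - 1) * i / 2) + i
    x <- perm[i, , drop = FALSE]; y <- perm[j, , drop = FALSE]
    xc <- x - rowMeans(x); yc <- y - rowMeans(y)
    num <- rowSums(xc * yc)
    den <- sqrt(rowSums(xc^2) * rowSums(yc^2))
    r <- ifelse(den > 0, num / den, NA_real_)
    draws[[s]] <- r
  }
  r <- unlist(draws)
  dropped <- sum(is.na(r))
  structure(list(r = r[!is.na(r)], n_pairs = n_pairs, n_shuffles = n_shuffles,
                 n_dropped = dropped, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("permutation null: %d r draws (%d x %d, %d dropped), mean %.4f\n",
              length(x$r), x$n_pairs, x$n_shuffles, x$n_dropped, mean(x$r)))
  invisible(x)
}

#' Empirical FDR of a correlation threshold from the permutation null
#'
#' The tail fraction `P_null(|r| >= r_min)` scaled by the ratio of the pair
#' universes: an estimate of the expected share of edges at the threshold
#' that the shuffled data would produce.
#'
#' @param null [permutation_null()] result.
#' @param observed data.frame from [pairwise_correlations()].
#' @param r_min threshold (default 0.95).
#' @return list with `null_tail`, `observed_tail`, `empirical_fdr`.
#' @export
empirical_fdr <- function(null, observed, r_min = 0.95) {
  nt <- mean(abs(null$r) >= r_min)
  ot <- mean(abs(observed$r) >= r_min, na.rm = TRUE)
  list(null_tail = nt, observed_tail = ot,
       empirical_fdr = if (ot > 0) min(nt / ot, 1) else NA_real_)
}

#' Build the filtered co-regulation network
#'
#' Benjamini-Hochberg adjustment is computed over ALL tested pairs (the full
#' pair universe, not only those passing the correlation gate); pairs with
#' `|r| >= r_min` and `p_adj < alpha` become edges.
#'
#' @param pairs data.frame from [pairwise_correlations()] (or any table with
#'   `protein_a`, `protein_b`, `r`, `p_raw`).
#' @param r_min absolute-correlation threshold (default 0.95).
#' @param alpha BH-adjusted p threshold (default 0.01).
#' @param nodes node universe; defaults to all features appearing in `pairs`.
#' @param n_samples provenance: samples the correlations used.
#' @return [correlation_network()]
#' @export
build_network <- function(pairs, r_min = 0.95, alpha = 0.01, nodes = NULL,
                          n_samples = NA_integer_) {
  ok <- !is.na(pairs$r)
  p_adj <- rep(NA_real_, nrow(pairs))
  p_adj[ok] <- stats::p.adjust(pairs$p_raw[ok], method = "BH")
  keep <- ok & abs(pairs$r) >= r_min & p_adj < alpha
  edges <- pairs[keep, c("protein_a", "protein_b", "r", "p_raw"), drop = FALSE]
  edges$p_adj <- p_adj[keep]
  edges$sign <- ifelse(edges$r > 0, "positive", "negative")
  nodes <- nodes %||% unique(c(pairs$protein_a, pairs$protein_b))
  correlation_network(edges, nodes = nodes, r_min = r_min, alpha = alpha,
                      n_samples = n_samples)
}

#' Correlation network straight from an abundance matrix
#'
#' Convenience wrapper: [pairwise_correlations()] then [build_network()],
#' keeping the full feature set as the node universe.
#'
#' @inheritParams pairwise_correlations
#' @inheritParams build_network
#' @return [correlation_network()]
#' @export
coregulation_network <- function(am, r_min = 0.95, alpha = 0.01, block_size = 512) {
  pairs <- pairwise_correlations(am, block_size = block_size)
  build_network(pairs, r_min = r_min, alpha = alpha, nodes = rownames(am$values),
                n_samples = ncol(am$values))
}

# incidence-based count of node pairs sharing >= 1 set of a collection;
# returns a logical adjacency over `nodes` (used by annotation ops)
shared_set_adjacency <- function(nodes, sets) {
  inc <- matrix(FALSE, length(nodes), length(sets),
                dimnames = list(nodes, names(sets)))
  for (k in seq_along(sets)) {
    inc[intersect(sets[[k]], nodes), k] <- TRUE
  }
  tcrossprod(inc) > 0
}

#' Annotate network edges against gene-set categories and a PPI table
#'
#' An edge is annotated under a category iff both endpoints share at least
#' one gene set of that category; for the `ppi` category, iff the pair
#' appears in the interaction table. Reports per-edge flags and per-category
#' fractions of annotated positive, negative and all edges, plus the
#' fraction of edges annotated under at least one category.
#'
#' @param net [correlation_network()]
#' @param collections named list of [gene_set_collection()]s; names are the
#'   category labels.
#' @param ppi optional data.frame with two columns of interacting feature
#'   IDs.
#' @return list with `edge_flags` (data.frame: edge columns + one logical
#'   column per category + `any_category`) and `category_summary`
#'   (data.frame: category, pct_positive_annotated, pct_negative_annotated,
#'   pct_all_annotated).
#' @export
annotate_edges <- function(net, collections, ppi = NULL) {
  stopifnot(inherits(net, "correlation_network"))
  e <- net$edges
  flags <- e[, c("protein_a", "protein_b", "r", "sign"), drop = FALSE]
  cats <- character()
  for (cat in names(collections)) {
    adj <- shared_set_adjacency(net$nodes, collections[[cat]]$sets)
    flags[[cat]] <- adj[cbind(e$protein_a, e$protein_b)]
    cats <- c(cats, cat)
  }
  if (!is.null(ppi) && nrow(ppi)) {
    keys <- pair_key(as.character(ppi[[1]]), as.character(ppi[[2]]))
    flags$ppi <- pair_key(e$protein_a, e$protein_b) %in% keys
    cats <- c(cats, "ppi")
  }
  flags$any_category <- if (length(cats)) {
    Reduce(`|`, flags[cats])
  } else rep(FALSE, nrow(e))
  pct <- function(x, sub) if (any(sub)) 100 * mean(x[sub]) else NA_real_
  pos <- flags$sign == "positive"
  category_summary <- do.call(rbind, lapply(c(cats, "any_category"), function(cat) {
    data.frame(category = cat,
               pct_positive_annotated = pct(flags[[cat]], pos),
               pct_negative_annotated = pct(flags[[cat]], !pos),
               pct_all_annotated = pct(flags[[cat]], rep(TRUE, nrow(flags))),
               stringsAsFactors = FALSE)
  }))
  list(edge_flags = flags, category_summary = category_summary)
}

#' Enrichment ratio of annotated edges over the all-pairs expectation
#'
#' The fraction of observed positive edges annotated under a category,
#' divided by the fraction of ALL possible pairs of network nodes annotated
#' under it. A ratio of 1 means the network carries no annotation signal; a
#' zero expected fraction makes the ratio undefined (`NA` with a warning).
#'
#' @param net [correlation_network()]
#' @param gsc [gene_set_collection()] for the category (or, for PPI, pass
#'   `ppi`).
#' @param ppi optional two-column interaction table (used instead of `gsc`).
#' @return list with `observed_fraction`, `expected_fraction`, `ratio`.
#' @export
annotation_enrichment_ratio <- function(net, gsc = NULL, ppi = NULL) {
  stopifnot(inherits(net, "correlation_network"))
  nodes <- net$nodes
  e <- net$edges[net$edges$sign == "positive", , drop = FALSE]
  if (!is.null(gsc)) {
    adj <- shared_set_adjacency(nodes, gsc$sets)
    obs <- if (nrow(e)) mean(adj[cbind(e$protein_a, e$protein_b)]) else NA_real_
    n_annot_pairs <- (sum(adj) - sum(diag(adj))) / 2
  } else if (!is.null(ppi)) {
    keys <- unique(pair_key(as.character(ppi[[1]]), as.character(ppi[[2]])))
    in_net <- keys[vapply(strsplit(keys, "\r", fixed = TRUE),
                          function(ab) all(ab %in% nodes) && ab[1] != ab[2],
                          logical(1))]
    obs <- if (nrow(e)) mean(pair_key(e$protein_a, e$protein_b) %in% in_net) else NA_real_
    n_annot_pairs <- length(in_net)
  } else stopf("provide gsc or ppi")
  expd <- n_annot_pairs / count_feature_pairs(length(nodes))
  if (!is.na(expd) && expd == 0) {
    warnf("expected annotated fraction is zero; ratio undefined")
    ratio <- NA_real_
  } else ratio <- obs / expd
  list(observed_fraction = obs, expected_fraction = expd, ratio = ratio)
}

#' Recovery of a known complex by the network
#'
#' How completely a complex is represented: members present in the network
#' node set, the share of possible within-complex pairs present as edges,
#' and the share of those edges that are positive. Complexes with fewer than
#' 3 members present are skipped (`NULL`), consistent with the gene-set
#' filtering rule.
#'
#' @param net [correlation_network()]
#' @param members character vector of complex member IDs.
#' @return list with `n_members_total`, `n_members_in_network`,
#'   `pct_possible_edges_present`, `pct_edges_positive` — or `NULL` when
#'   fewer than 3 members are in the network.
#' @export
complex_recovery <- function(net, members) {
  stopifnot(inherits(net, "correlation_network"))
  present <- intersect(members, net$nodes)
  if (length(present) < 3) return(NULL)
  e <- net$edges
  within <- e$protein_a %in% present & e$protein_b %in% present
  possible <- count_feature_pairs(length(present))
  n_within <- sum(within)
  list(n_members_total = length(members),
       n_members_in_network = length(present),
       pct_possible_edges_present = 100 * n_within / possible,
       pct_edges_positive = if (n_within) 100 * mean(e$sign[within] == "positive") else NA_real_)
}

#' Mean pairwise correlation within a gene set
#'
#' The arithmetic mean of Pearson r over ALL detected unordered pairs of set
#' members (not only pairs passing the network thresholds). Undefined (`NA`)
#' for sets with fewer than 2 detected members.
#'
#' @param am [abundance_matrix()] (complete over samples).
#' @param members character vector of member IDs.
#' @return mean r, or `NA` with a warning when < 2 members are detected.
#' @export
mean_set_correlation <- function(am, members) {
  stopifnot(inherits(am, "abundance_matrix"))
  present <- intersect(members, rownames(am$values))
  if (length(present) < 2) {
    warnf("fewer than 2 set members detected; mean correlation undefined")
    return(NA_real_)
  }
  cm <- stats::cor(t(am$values[present, , drop = FALSE]))
  mean(cm[upper.tri(cm)])
}
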