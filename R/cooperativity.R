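#' Cooperative proteins around known modules
#'
#' For every (candidate protein, module) combination — candidates being all
#' network nodes outside the module's detected membership — the network's
#' edge set is partitioned into a 2x2 table:
#' \describe{
#'   \item{a}{edges between the candidate and module members}
#'   \item{b}{edges touching the module but not the candidate (intra-module
#'     edges included)}
#'   \item{c}{edges touching the candidate but not the module}
#'   \item{d}{edges touching neither}
#' }
#' so that `a + b + c + d` equals the total edge count under test. A
#' one-sided (enrichment) Fisher's exact p-value tests whether the
#' candidate's edges concentrate on the module; BH adjustment is applied
#' jointly across ALL (candidate, module) tests. By default only positive
#' edges are counted (co-regulation in the same direction); `edge_sign =
#' "all"` uses every edge.
#'
#' @param net [correlation_network()]
#' @param modules [gene_set_collection()]; modules with fewer than 3
#'   detected members (in the network node set) are skipped with a message.
#' @param edge_sign `"positive"` (default) or `"all"`.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame of class `cooperativity_result` with columns
#'   `candidate`, `module`, `a`, `b`, `c`, `d`, `p_raw`, `p_adj`,
#'   `significant`, sorted by `p_adj`, then decreasing `a`, then candidate
#'   ID.
#' @export
cooperative_proteins <- function(net, modules, edge_sign = c("positive", "all"),
                                 alpha = 0.05) {
  stopifnot(inherits(net, "correlation_network"),
            inherits(modules, "gene_set_collection"))
  edge_sign <- match.arg(edge_sign)
  e <- net$edges
  if (edge_sign == "positive") e <- e[e$sign == "positive", , drop = FALSE]
  n_edges <- nrow(e)
  nodes <- net$nodes
  res <- list()
  for (nm in names(modules$sets)) {
    members <- intersect(detected_members(modules, nm), nodes)
    if (length(members) < 3) {
      message(sprintf("module %s skipped: fewer than 3 detected members in network", nm))
      next
    }
    in_mod_a <- e$protein_a %in% members
    in_mod_b <- e$protein_b %in% members
    intra <- sum(in_mod_a & in_mod_b)
    # edges between each outside node and the module
    touching <- c(e$protein_b[in_mod_a & !in_mod_b], e$protein_a[in_mod_b & !in_mod_a])
    cnt <- table(touching)
    candidates <- setdiff(nodes, members)
    a <- integer(length(candidates))
    names(a) <- candidates
    a[names(cnt)] <- as.integer(cnt)
    deg <- table(factor(c(e$protein_a, e$protein_b), levels = candidates))
    deg <- as.integer(deg)
    tot_mod <- intra + sum(a)
    b <- tot_mod - a
    cc <- deg - a
    d <- n_edges - a - b - cc
    # one-sided Fisher on fixed margins == hypergeometric upper tail
    p <- stats::phyper(a - 1, a + b, cc + d, a + cc, lower.tail = FALSE)
    res[[nm]] <- data.frame(candidate = candidates, module = nm,
                            a = unname(a), b = unname(b), c = cc, d = unname(d),
                            p_raw = unname(p), stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    out <- data.frame(candidate = character(), module = character(),
                      a = integer(), b = integer(), c = integer(), d = integer(),
                      p_raw = numeric(), p_adj = numeric(), significant = logical())
    class(out) <- c("cooperativity_result", class(out))
    return(out)
  }
  out <- do.call(rbind, res)
  stopifnot(all(out$a + out$b + out$c + out$d == n_edges))
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p_adj, -out$a, out$candidate), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cooperativity_result", class(out))
  out
}

#' Withheld-member validation of cooperativity detection
#'
#' Removes `withheld` members from a complex, reruns
#' [cooperative_proteins()] against the reduced module, and reports each
#' withheld member's rank among the module's candidates (by adjusted p, ties
#' broken by larger `a` then candidate ID). True members should surface at
#' the top.
#'
#' @param net [correlation_network()]
#' @param members full complex membership.
#' @param withheld subset of `members` to withhold (may be empty; withholding
#'   everything is an error).
#' @param ... passed to [cooperative_proteins()].
#' @return data.frame with `member`, `rank`, `p_adj`, `a` for each withheld
#'   member (rank `NA` if the member is not a network node).
#' @export
withheld_member_validation <- function(net, members, withheld, ...) {
  if (length(setdiff(members, withheld)) == 0) stopf("cannot withhold every member")
  reduced <- setdiff(members, withheld)
  gsc <- gene_set_collection(list(reduced_module = reduced), source = "complex")
  res <- cooperative_proteins(net, gsc, ...)
  res$rank <- seq_len(nrow(res))
  idx <- match(withheld, res$candidate)
  data.frame(member = withheld,
             rank = res$rank[idx],
             p_adj = res$p_adj[idx],
             a = res$a[idx],
             stringsAsFactors = FALSE)
}

#' Jaccard overlap of cooperative-protein sets between modules
#'
#' For every module pair, the Jaccard similarity of their significant
#' cooperative-protein sets, plus a hierarchical clustering of the matrix
#' (Euclidean distance, average linkage). Modules with no significant
#' cooperative proteins keep a row of zeros and are flagged.
#'
#' @param results [cooperative_proteins()] output.
#' @return list with `jaccard` (module x module matrix), `hclust`
#'   ([stats::hclust] object, `NULL` for < 2 modules) and `empty_modules`.
#' @export
shared_cooperativity <- function(results) {
  mods <- unique(results$module)
  coop <- lapply(mods, function(m) {
    results$candidate[results$module == m & results$significant]
  })
  names(coop) <- mods
  J <- matrix(0, length(mods), length(mods), dimnames = list(mods, mods))
  for (i in seq_along(mods)) for (j in seq_along(mods)) {
    u <- union(coop[[i]], coop[[j]])
    J[i, j] <- if (length(u)) length(intersect(coop[[i]], coop[[j]])) / length(u) else 0
  }
  diag(J) <- 1
  hc <- if (length(mods) >= 2) stats::hclust(stats::dist(J), method = "average")
  list(jaccard = J, hclust = hc,
       empty_modules = mods[lengths(coop) == 0])
}

#' PPI support for significant cooperative relationships
#'
#' A significant (candidate, module) result is supported iff the interaction
#' table lists the candidate with at least one detected module member.
#'
#' @param results [cooperative_proteins()] output.
#' @param modules the [gene_set_collection()] used to produce `results`.
#' @param ppi two-column data.frame of interacting feature IDs.
#' @return list with `per_result` (results subset to significant rows plus a
#'   `ppi_supported` flag), `fraction_supported` (of significant results) and
#'   `fraction_proteins_supported` (of distinct significant candidates).
#' @export
ppi_support <- function(results, modules, ppi) {
  sig <- results[results$significant, , drop = FALSE]
  keys <- unique(pair_key(as.character(ppi[[1]]), as.character(ppi[[2]])))
  supported <- vapply(seq_len(nrow(sig)), function(i) {
    members <- detected_members(modules, sig$module[i])
    any(pair_key(rep(sig$candidate[i], length(members)), members) %in% keys)
  }, logical(1))
  sig$ppi_supported <- supported
  prot_supported <- tapply(supported, sig$candidate, any)
  list(per_result = sig,
       fraction_supported = if (nrow(sig)) mean(supported) else NA_real_,
       fraction_proteins_supported = if (nrow(sig)) mean(prot_supported) else NA_real_)
}
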