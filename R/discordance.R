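#' Per-gene RNA-protein correlation across paired conditions
#'
#' Both matrices are reduced to per-condition means (by default group x
#' stage), conditions present in both assays are paired, and a per-gene
#' Pearson correlation is computed across them for every gene present in
#' both matrices. Also reports the global mean r.
#'
#' @param protein,rna log2-ratio [abundance_matrix()] objects.
#' @param condition_by sample-sheet columns defining the condition axis
#'   (default `c("cell_line", "stage")`).
#' @return list with `per_gene` (data.frame gene/r), `mean_r`,
#'   `n_conditions`.
#' @export
per_gene_rna_protein_correlation <- function(protein, rna,
                                             condition_by = c("cell_line", "stage")) {
  pm <- condition_means(protein, condition_by)
  rm_ <- condition_means(rna, condition_by)
  conds <- intersect(colnames(pm), colnames(rm_))
  if (length(conds) < 3) stopf("need at least 3 paired conditions (have %d)", length(conds))
  genes <- intersect(rownames(pm), rownames(rm_))
  pv <- pm[genes, conds, drop = FALSE]
  rv <- rm_[genes, conds, drop = FALSE]
  pc <- pv - rowMeans(pv); rc <- rv - rowMeans(rv)
  num <- rowSums(pc * rc)
  den <- sqrt(rowSums(pc^2) * rowSums(rc^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  per_gene <- data.frame(gene = genes, r = unname(r), stringsAsFactors = FALSE)
  list(per_gene = per_gene, mean_r = mean(r, na.rm = TRUE),
       n_conditions = length(conds))
}

#' RNA-protein discordance per gene and stage
#'
#' Discordance `D = protein_fc - rna_fc`: the log2-transformed ratio of the
#' mean protein fold change to the mean RNA fold change at each stage, with
#' fold changes taken against a common baseline. `D = 0` means concordant
#' regulation; `D >= threshold` classifies the gene as protein-abundant at
#' that stage, `D <= -threshold` as RNA-abundant. Replicate means are taken
#' within each assay before the difference, so unbalanced replication (e.g.
#' 3 protein vs 2 RNA replicates) needs no special handling.
#'
#' Baselines: with `reference = "geomean"` (the default, matching the
#' normalization convention) each assay's log2 ratios are already fold
#' changes to the per-gene geometric mean, and per-gene discordance sums to
#' zero across stages — only stage-contrasts of an offset are identifiable.
#' With `reference = "stage"` fold changes are re-expressed against
#' `ref_stage`, making a single-stage offset recoverable exactly.
#'
#' @param protein,rna log2-ratio [abundance_matrix()] objects over the same
#'   gene namespace.
#' @param threshold classification threshold in log2 units (default 1).
#' @param reference `"geomean"` or `"stage"`.
#' @param ref_stage reference stage label (required for
#'   `reference = "stage"`).
#' @return list with `records` (data.frame gene/stage/protein_fc/rna_fc/
#'   discordance/class) and `coverage` (genes in both assays vs. either).
#' @export
compute_discordance <- function(protein, rna, threshold = 1,
                                reference = c("geomean", "stage"),
                                ref_stage = NULL) {
  stopifnot(inherits(protein, "abundance_matrix"), inherits(rna, "abundance_matrix"))
  if (protein$scale != "log2_ratio" || rna$scale != "log2_ratio") {
    stopf("both matrices must be on log2_ratio scale")
  }
  reference <- match.arg(reference)
  pm <- stage_means(protein)
  rm_ <- stage_means(rna)
  stages <- intersect(colnames(pm), colnames(rm_))
  genes <- intersect(rownames(pm), rownames(rm_))
  skipped <- length(union(rownames(pm), rownames(rm_))) - length(genes)
  pv <- pm[genes, stages, drop = FALSE]
  rv <- rm_[genes, stages, drop = FALSE]
  if (reference == "stage") {
    if (is.null(ref_stage) || !ref_stage %in% stages) {
      stopf("reference = 'stage' needs a ref_stage present in both assays")
    }
    pv <- pv - pv[, ref_stage]
    rv <- rv - rv[, ref_stage]
  }
  D <- pv - rv
  records <- data.frame(
    gene = rep(genes, times = length(stages)),
    stage = rep(stages, each = length(genes)),
    protein_fc = as.vector(pv),
    rna_fc = as.vector(rv),
    discordance = as.vector(D),
    stringsAsFactors = FALSE)
  records$class <- ifelse(records$discordance >= threshold, "protein_abundant",
                          ifelse(records$discordance <= -threshold,
                                 "rna_abundant", "concordant"))
  list(records = records,
       coverage = list(n_shared = length(genes), n_skipped = skipped))
}

#' Complex-level summaries of RNA-protein agreement
#'
#' Two statistics per complex over its detected members (complexes with
#' fewer than 3 members detected in both inputs are excluded, consistent
#' with the gene-set filter): the median per-gene RNA-protein correlation,
#' and the median per-stage discordance.
#'
#' @param per_gene_r data.frame gene/r from
#'   [per_gene_rna_protein_correlation()].
#' @param records discordance records from [compute_discordance()].
#' @param complexes [gene_set_collection()]
#' @return data.frame with `complex`, `n_members`, `median_r`, and one
#'   `median_D_<stage>` column per stage.
#' @export
complex_discordance_summary <- function(per_gene_r, records, complexes) {
  stopifnot(inherits(complexes, "gene_set_collection"))
  stages <- unique(records$stage)
  rows <- lapply(names(complexes$sets), function(nm) {
    members <- intersect(detected_members(complexes, nm),
                         intersect(per_gene_r$gene, records$gene))
    if (length(members) <= 2) return(NULL)
    med_r <- stats::median(per_gene_r$r[per_gene_r$gene %in% members], na.rm = TRUE)
    medD <- vapply(stages, function(s) {
      stats::median(records$discordance[records$gene %in% members & records$stage == s],
                    na.rm = TRUE)
    }, numeric(1))
    out <- data.frame(complex = nm, n_members = length(members), median_r = med_r,
                      stringsAsFactors = FALSE)
    out[paste0("median_D_", stages)] <- as.list(medD)
    out
  })
  do.call(rbind, rows)
}

#' Stage-transition discordance test per complex
#'
#' For each complex, each member's log2 fold change from `stage_a` to
#' `stage_b` is computed in the protein and RNA assays; the paired
#' member-wise differences (protein FC minus RNA FC) are tested against 0
#' (two-sided paired t by default, or an unpaired two-sample t across the
#' two FC sets). BH adjustment across complexes. Complexes with fewer than
#' 3 members measured in both assays are skipped.
#'
#' @param protein,rna log2-ratio [abundance_matrix()] objects.
#' @param complexes [gene_set_collection()]
#' @param stage_a,stage_b transition endpoints (FC is b minus a).
#' @param method `"paired_t"` (default) or `"two_sample"`.
#' @return data.frame with `complex`, `n_members`, `mean_protein_fc`,
#'   `mean_rna_fc`, `mean_diff`, `p_raw`, `p_adj`.
#' @export
stage_transition_discordance_test <- function(protein, rna, complexes,
                                              stage_a, stage_b,
                                              method = c("paired_t", "two_sample")) {
  stopifnot(inherits(complexes, "gene_set_collection"))
  method <- match.arg(method)
  pm <- stage_means(protein)
  rm_ <- stage_means(rna)
  for (s in c(stage_a, stage_b)) {
    if (!s %in% colnames(pm) || !s %in% colnames(rm_)) stopf("stage %s missing from an assay", s)
  }
  genes <- intersect(rownames(pm), rownames(rm_))
  pfc <- pm[genes, stage_b] - pm[genes, stage_a]
  rfc <- rm_[genes, stage_b] - rm_[genes, stage_a]
  rows <- lapply(names(complexes$sets), function(nm) {
    members <- intersect(detected_members(complexes, nm), genes)
    if (length(members) < 3) return(NULL)
    pf <- pfc[members]; rf <- rfc[members]
    dd <- pf - rf
    p <- if (method == "paired_t") {
      # degenerate zero-variance differences: exactly concordant -> p = 1,
      # constant nonzero shift -> p = 0
      if (stats::sd(dd) == 0) as.numeric(mean(dd) == 0) else
        stats::t.test(dd)$p.value
    } else {
      stats::t.test(pf, rf)$p.value
    }
    data.frame(complex = nm, n_members = length(members),
               mean_protein_fc = mean(pf), mean_rna_fc = mean(rf),
               mean_diff = mean(dd), p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out[order(out$p_adj), , drop = FALSE]
}

#' Transcript targets tracking a transcription factor's protein profile
#'
#' Correlates the TF's protein profile (per-condition means) with every
#' transcript's profile, keeps annotated targets with `r >= r_min`, labels
#' each retained target with the stage of its maximum transcript abundance,
#' and summarizes how the retained targets distribute over stages.
#'
#' @param tf TF feature ID (must be in the protein matrix).
#' @param protein,rna log2-ratio [abundance_matrix()] objects.
#' @param targets character vector of annotated target transcript IDs for
#'   the TF.
#' @param r_min correlation cut-off (default 0.9).
#' @param condition_by condition axis columns (default
#'   `c("cell_line", "stage")`).
#' @return list with `targets` (data.frame gene/r/argmax_stage),
#'   `stage_counts` (targets per argmax stage) and `tf_argmax_stage`.
#' @export
tf_target_concordance <- function(tf, protein, rna, targets, r_min = 0.9,
                                  condition_by = c("cell_line", "stage")) {
  pm <- condition_means(protein, condition_by)
  if (!tf %in% rownames(pm)) stopf("TF %s absent from the protein matrix", tf)
  rm_ <- condition_means(rna, condition_by)
  conds <- intersect(colnames(pm), colnames(rm_))
  if (length(conds) < 3) stopf("need at least 3 paired conditions")
  prof <- pm[tf, conds]
  cand <- intersect(targets, rownames(rm_))
  rv <- rm_[cand, conds, drop = FALSE]
  r <- suppressWarnings(apply(rv, 1, function(x) stats::cor(x, prof)))
  keep <- !is.na(r) & r >= r_min
  kept <- cand[keep]
  rna_stage <- stage_means(rna)
  argmax <- colnames(rna_stage)[apply(rna_stage[kept, , drop = FALSE], 1, which.max)]
  prot_stage <- stage_means(protein)
  tf_argmax <- colnames(prot_stage)[which.max(prot_stage[tf, ])]
  list(targets = data.frame(gene = kept, r = unname(r[keep]),
                            argmax_stage = if (length(kept)) argmax else character(),
                            stringsAsFactors = FALSE),
       stage_counts = table(factor(argmax, levels = colnames(rna_stage))),
       tf_argmax_stage = tf_argmax)
}
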