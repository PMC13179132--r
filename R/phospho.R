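#' Phosphosite-by-sample matrix
#'
#' An [abundance_matrix()] whose features are phosphosites, each mapping to
#' exactly one host protein with a residue (S/T/Y) and 1-based position.
#' Site IDs are serialized as `"<PROTEIN>_<residue><position>"` (e.g.
#' `UTF1_T35`). Duplicate (protein, residue, position) triples are rejected.
#'
#' @param values numeric matrix, sites in rows (rownames = site IDs).
#' @param sites data.frame with `site_id`, `protein`, `residue`, `position`.
#' @param samples sample sheet (as for [abundance_matrix()]).
#' @param scale `"raw"` or `"log2_ratio"`.
#' @return object of classes `phosphosite_matrix`, `abundance_matrix`.
#' @export
phosphosite_matrix <- function(values, sites, samples, scale = c("raw", "log2_ratio")) {
  am <- abundance_matrix(values, samples, scale = match.arg(scale))
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  req <- c("site_id", "protein", "residue", "position")
  if (!all(req %in% names(sites))) stopf("sites needs columns: %s", paste(req, collapse = ", "))
  if (!all(sites$residue %in% c("S", "T", "Y"))) stopf("residues must be S, T or Y")
  if (any(sites$position < 1)) stopf("positions must be positive")
  key <- paste(sites$protein, sites$residue, sites$position)
  if (anyDuplicated(key)) stopf("duplicate (protein, residue, position) sites")
  sites <- sites[match(rownames(am$values), sites$site_id), , drop = FALSE]
  if (anyNA(sites$site_id)) stopf("sites table does not cover every matrix row")
  rownames(sites) <- NULL
  am$sites <- sites
  class(am) <- c("phosphosite_matrix", class(am))
  am
}

#' Parse `"PROTEIN_S123"`-style site IDs
#'
#' @param site_ids character vector.
#' @return data.frame with `site_id`, `protein`, `residue`, `position`.
#' @export
parse_site_ids <- function(site_ids) {
  m <- regmatches(site_ids, regexec("^(.*)_([STY])([0-9]+)$", site_ids))
  bad <- lengths(m) != 4
  if (any(bad)) stopf("malformed site IDs: %s", paste(site_ids[bad], collapse = ", "))
  data.frame(site_id = site_ids,
             protein = vapply(m, `[`, character(1), 2),
             residue = vapply(m, `[`, character(1), 3),
             position = as.integer(vapply(m, `[`, character(1), 4)),
             stringsAsFactors = FALSE)
}

#' Read a phosphosite matrix from TSV
#'
#' Like [read_abundance_matrix()] but the first column holds
#' `"PROTEIN_S123"`-style site IDs, parsed into the site table.
#'
#' @inheritParams read_abundance_matrix
#' @return [phosphosite_matrix()]
#' @export
read_phosphosite_matrix <- function(path, sample_sheet, scale = c("raw", "log2_ratio"),
                                    stage_levels = NULL) {
  am <- read_abundance_matrix(path, sample_sheet, scale = scale,
                              stage_levels = stage_levels)
  phosphosite_matrix(am$values, parse_site_ids(rownames(am$values)),
                     am$samples, scale = am$scale)
}

# 1:1 alignment of two sample sheets on (species, cell_line, stage, replicate);
# returns column indices of `from` matching each column of `to`.
match_sample_layout <- function(to, from) {
  key <- function(s) paste(s$species, s$cell_line, as.character(s$stage),
                           s$replicate, sep = "|")
  idx <- match(key(to), key(from))
  if (anyNA(idx) || anyDuplicated(idx)) {
    stopf("sample layouts do not align 1:1 on (species, cell_line, stage, replicate)")
  }
  idx
}

#' Subtract host-protein log2 ratios from phosphosite log2 ratios
#'
#' Per sample, each site's value becomes `site - host protein`, isolating
#' protein-independent phosphorylation changes. Sites whose host protein is
#' not quantified are retained unnormalized and flagged. Samples are aligned
#' 1:1 on (species, cell_line, stage, replicate); any mismatch is an error.
#'
#' @param pm log2-ratio [phosphosite_matrix()]
#' @param proteins log2-ratio [abundance_matrix()]
#' @return `phosphosite_matrix` with an added logical `normalized` column in
#'   the site table.
#' @export
protein_normalize_sites <- function(pm, proteins) {
  stopifnot(inherits(pm, "phosphosite_matrix"), inherits(proteins, "abundance_matrix"))
  if (pm$scale != "log2_ratio" || proteins$scale != "log2_ratio") {
    stopf("both inputs must be on log2_ratio scale")
  }
  idx <- match_sample_layout(pm$samples, proteins$samples)
  pv <- proteins$values[, idx, drop = FALSE]
  have_host <- pm$sites$protein %in% rownames(pv)
  out <- pm$values
  out[have_host, ] <- out[have_host, , drop = FALSE] -
    pv[pm$sites$protein[have_host], , drop = FALSE]
  res <- phosphosite_matrix(out, pm$sites, pm$samples, scale = "log2_ratio")
  res$sites$normalized <- have_host
  res
}

#' Kinase-substrate enrichment (KSEA) z-scores
#'
#' Input sites should be protein-normalized log2 ratios; each site row is
#' first centred on its row mean (the fold change to the row mean across all
#' samples), then per sample each kinase with `m >= min_substrates` mapped
#' sites present scores
#' \deqn{z = (\bar{s} - \bar{p}) \sqrt{m} / \delta}
#' where \eqn{\bar{s}} is the mean over the kinase's substrate sites,
#' \eqn{\bar{p}} the mean over all sites, and \eqn{\delta} the standard
#' deviation (n-1 convention) over all sites in that sample. Kinases below
#' the substrate cutoff are omitted. The score is invariant to adding a
#' constant to all site values.
#'
#' @param pm log2-ratio [phosphosite_matrix()] (protein-normalized).
#' @param ks_map data.frame with `kinase` and `site_id` columns (as from
#'   [read_ks_map()]).
#' @param min_substrates minimum mapped sites per kinase (default 2).
#' @return list with `z` (kinase x sample matrix) and `n_substrates` (named
#'   integer vector).
#' @export
ksea_zscores <- function(pm, ks_map, min_substrates = 2) {
  stopifnot(inherits(pm, "phosphosite_matrix"))
  if (!nrow(pm$values)) stopf("empty site matrix")
  v <- pm$values - rowMeans(pm$values, na.rm = TRUE)
  ks <- ks_map[ks_map$site_id %in% rownames(v), , drop = FALSE]
  m <- table(ks$kinase)
  kin <- names(m)[m >= min_substrates]
  if (!length(kin)) {
    return(list(z = matrix(numeric(), 0, ncol(v), dimnames = list(NULL, colnames(v))),
                n_substrates = integer()))
  }
  p_bar <- colMeans(v, na.rm = TRUE)
  delta <- apply(v, 2, stats::sd, na.rm = TRUE)
  z <- t(vapply(kin, function(k) {
    subs <- ks$site_id[ks$kinase == k]
    s_bar <- colMeans(v[subs, , drop = FALSE], na.rm = TRUE)
    (s_bar - p_bar) * sqrt(length(subs)) / delta
  }, numeric(ncol(v))))
  rownames(z) <- kin
  list(z = z, n_substrates = stats::setNames(as.integer(m[kin]), kin))
}

#' Kinase-substrate correlation network
#'
#' Pearson correlation between each annotated kinase's profile (by default
#' its protein abundance profile) and each of its substrate sites' profiles,
#' over the aligned samples; pairs with `|r| >= r_min` are retained with
#' their sign. Constant profiles on either side are dropped (undefined r).
#'
#' @param kinases log2-ratio [abundance_matrix()] holding kinase profiles
#'   (protein abundances, or a per-contrast activity series).
#' @param pm log2-ratio [phosphosite_matrix()] of substrate site profiles.
#' @param ks_map data.frame with `kinase` and `site_id` columns.
#' @param r_min absolute-correlation threshold (default 0.5).
#' @return data.frame with `kinase`, `site_id`, `r`, `sign`.
#' @export
kinase_substrate_network <- function(kinases, pm, ks_map, r_min = 0.5) {
  stopifnot(inherits(kinases, "abundance_matrix"), inherits(pm, "phosphosite_matrix"))
  idx <- match_sample_layout(pm$samples, kinases$samples)
  kv <- kinases$values[, idx, drop = FALSE]
  ks <- ks_map[ks_map$site_id %in% rownames(pm$values) &
                 ks_map$kinase %in% rownames(kv), , drop = FALSE]
  if (!nrow(ks)) {
    return(data.frame(kinase = character(), site_id = character(),
                      r = numeric(), sign = character()))
  }
  r <- vapply(seq_len(nrow(ks)), function(i) {
    x <- kv[ks$kinase[i], ]
    y <- pm$values[ks$site_id[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  keep <- !is.na(r) & abs(r) >= r_min
  data.frame(kinase = ks$kinase[keep], site_id = ks$site_id[keep],
             r = r[keep], sign = ifelse(r[keep] > 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Correlation of phosphosites with their host proteins
#'
#' Per-site Pearson correlation across aligned samples between the
#' (un-normalized) site profile and the host protein profile, with the
#' distribution's median. Sites without a quantified host are skipped.
#'
#' @param pm log2-ratio [phosphosite_matrix()]
#' @param proteins log2-ratio [abundance_matrix()]
#' @return list with `per_site` (data.frame site_id/protein/r) and
#'   `median_r`.
#' @export
site_protein_correlation <- function(pm, proteins) {
  stopifnot(inherits(pm, "phosphosite_matrix"), inherits(proteins, "abundance_matrix"))
  idx <- match_sample_layout(pm$samples, proteins$samples)
  pv <- proteins$values[, idx, drop = FALSE]
  keep <- pm$sites$protein %in% rownames(pv)
  sites <- pm$sites[keep, , drop = FALSE]
  r <- vapply(seq_len(nrow(sites)), function(i) {
    x <- pm$values[sites$site_id[i], ]
    y <- pv[sites$protein[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  list(per_site = data.frame(site_id = sites$site_id, protein = sites$protein,
                             r = r, stringsAsFactors = FALSE),
       median_r = stats::median(r, na.rm = TRUE))
}

#' Collapse duplicate phosphopeptide measurements to site level
#'
#' Multiple rows mapping to the same (protein, residue, position) are
#' collapsed by the per-sample median before analysis.
#'
#' @param values numeric matrix with site-ID rownames (possibly duplicated).
#' @param sites site table with one row per matrix row.
#' @param samples sample sheet.
#' @param scale scale tag.
#' @return [phosphosite_matrix()] with unique sites.
#' @export
collapse_phosphopeptides <- function(values, sites, samples,
                                     scale = c("raw", "log2_ratio")) {
  key <- paste(sites$protein, sites$residue, sites$position)
  if (!anyDuplicated(key)) return(phosphosite_matrix(values, sites, samples, scale))
  split_idx <- split(seq_len(nrow(values)), key)
  first <- vapply(split_idx, `[`, integer(1), 1)
  collapsed <- t(vapply(split_idx, function(ix) {
    apply(values[ix, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  }, numeric(ncol(values))))
  sites2 <- sites[first, , drop = FALSE]
  rownames(collapsed) <- sites2$site_id
  phosphosite_matrix(collapsed, sites2, samples, scale = match.arg(scale))
}
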