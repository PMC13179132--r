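#' Configuration for the synthetic multi-omics generator
#'
#' Describes a stage-structured experiment (stages x replicates x
#' groups/cell-lines) with planted structure at every level the pipeline is
#' meant to recover: co-regulated protein modules with fixed stage profiles,
#' anticorrelated module pairs, cooperative satellite proteins tracking a
#' module from outside it, per-gene RNA-protein discordance offsets, and
#' kinase-driven phosphosite programs. All noise is Gaussian on the log2
#' scale; raw intensities are `2^(log2 profile + per-gene base abundance)`.
#'
#' Noise model: each module member gets a per-gene abundance intercept drawn
#' once from `Normal(0, module sd)` (member-to-member offsets, removed by
#' ratio normalization) and i.i.d. per-sample measurement noise
#' `Normal(0, replicate_sd)`. Background genes get stage profiles drawn
#' independently per group from `Normal(0, background_profile_sd)`, making
#' them noise-dominated rather than strongly stage-driven. Satellites track
#' `strength x` the module profile with their own extra per-sample noise.
#'
#' @param n_background number of unstructured background genes.
#' @param modules named list; each element a list with `size` (>= 3),
#'   `profile` (numeric, length `n_stages`, log2 units), `sd` (per-gene
#'   intercept sd).
#' @param anticorrelated_pairs list of 2-vectors of module names; the second
#'   module's profile is set to the negated profile of the first.
#' @param cooperative list of lists with `module`, `n` (satellites),
#'   `strength` (correlation strength in \eqn{[-1,1]} scaling the module
#'   profile), `sd` (extra per-sample noise).
#' @param stages stage labels, ordered (length defines `n_stages`).
#' @param n_replicates protein replicates per group x stage.
#' @param rna_replicates RNA replicates per group x stage (fewer than protein
#'   by default, forcing downstream ops to handle unbalanced replication).
#' @param n_groups number of cell lines/groups.
#' @param replicate_sd per-sample measurement noise sd (log2 units).
#' @param background_profile_sd sd of background genes' per-group stage
#'   profiles.
#' @param rna_concordance scalar or named per-gene multiplier in
#'   \eqn{[-1,1]} applied to the protein profile to form the RNA profile.
#' @param rna_sd RNA per-sample noise sd.
#' @param discordance_offsets named list: gene ID -> numeric vector of
#'   additive log2 offsets per stage (protein minus RNA). `NULL` plants none.
#' @param phospho list with `kinases` (named list of `n_sites`, `activity`
#'   profile (length `n_stages`), `sd`), `n_background_sites`, `site_sd`.
#'   `NULL` disables the phospho layer.
#' @param seed integer seed; all three generators derive their streams from
#'   it (base R Mersenne-Twister), so the full bundle is reproducible.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_background = 40,
                             modules = list(
                               moduleA = list(size = 10, profile = c(0, 1, 2), sd = 0.1),
                               moduleB = list(size = 10, profile = c(0, -1, -2), sd = 0.1)),
                             anticorrelated_pairs = list(c("moduleA", "moduleB")),
                             cooperative = list(
                               list(module = "moduleA", n = 1, strength = 1.0, sd = 0.05),
                               list(module = "moduleB", n = 1, strength = 1.0, sd = 0.05)),
                             stages = c("primed", "early", "late"),
                             n_replicates = 3,
                             rna_replicates = 2,
                             n_groups = 2,
                             replicate_sd = 0.1,
                             background_profile_sd = 0.25,
                             rna_concordance = 1,
                             rna_sd = 0.1,
                             discordance_offsets = default_discordance_offsets(),
                             phospho = list(
                               kinases = list(
                                 KIN_ACT = list(n_sites = 6, activity = c(0, 2, 0.5), sd = 0.05),
                                 KIN_NULL1 = list(n_sites = 6, activity = c(0, 0, 0), sd = 0.05),
                                 KIN_NULL2 = list(n_sites = 5, activity = c(0, 0, 0), sd = 0.05)),
                               n_background_sites = 25,
                               site_sd = 0.1),
                             seed = 1L) {
  n_stages <- length(stages)
  for (nm in names(modules)) {
    m <- modules[[nm]]
    if (m$size < 3) stopf("module %s has size < 3", nm)
    if (length(m$profile) != n_stages) stopf("module %s profile length != n_stages", nm)
    if (m$sd < 0) stopf("module %s sd < 0", nm)
  }
  for (p in anticorrelated_pairs) {
    if (!all(p %in% names(modules))) stopf("anticorrelated pair names unknown module")
  }
  for (cc in cooperative) {
    if (!cc$module %in% names(modules)) stopf("cooperative entry names unknown module")
  }
  if (replicate_sd < 0 || rna_sd < 0 || background_profile_sd < 0) stopf("sd must be >= 0")
  if (!is.null(phospho)) {
    for (nm in names(phospho$kinases)) {
      k <- phospho$kinases[[nm]]
      if (k$n_sites < 1) stopf("kinase %s has no substrate sites", nm)
      if (length(k$activity) != n_stages) stopf("kinase %s activity length != n_stages", nm)
    }
  }
  structure(list(n_background = n_background, modules = modules,
                 anticorrelated_pairs = anticorrelated_pairs,
                 cooperative = cooperative, stages = stages,
                 n_stages = n_stages, n_replicates = n_replicates,
                 rna_replicates = rna_replicates, n_groups = n_groups,
                 replicate_sd = replicate_sd,
                 background_profile_sd = background_profile_sd,
                 rna_concordance = rna_concordance, rna_sd = rna_sd,
                 discordance_offsets = discordance_offsets,
                 phospho = phospho, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default planted discordance offsets
#'
#' Ten background genes carry a 2-log2-unit offset at a single stage: five
#' protein-abundant at the middle stage, five RNA-abundant at the last.
#' @return named list gene -> per-stage offset vector.
#' @export
default_discordance_offsets <- function() {
  off <- c(lapply(sprintf("BG_%03d", 1:5), function(g) c(0, 2, 0)),
           lapply(sprintf("BG_%03d", 6:10), function(g) c(0, 0, -2)))
  names(off) <- sprintf("BG_%03d", 1:10)
  off
}

group_names <- function(cfg) sprintf("line%s", LETTERS[seq_len(cfg$n_groups)])

sample_sheet_for <- function(cfg, assay, n_reps, prefix) {
  grid <- expand.grid(replicate = seq_len(n_reps), stage = cfg$stages,
                      cell_line = group_names(cfg), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(
    sample_id = sprintf("%s_%s_%s_r%d", prefix, grid$cell_line, grid$stage, grid$replicate),
    species = "synthetic",
    cell_line = grid$cell_line,
    stage = factor(grid$stage, levels = cfg$stages, ordered = TRUE),
    replicate = grid$replicate,
    assay = assay,
    stringsAsFactors = FALSE)
}

# True mean log2 stage profiles for every gene: array [gene, stage, group],
# plus the role table. Deterministic given the seed (drawn inside
# generate_proteome's RNG stream).
build_truth_profiles <- function(cfg) {
  mods <- cfg$modules
  for (p in cfg$anticorrelated_pairs) {
    mods[[p[2]]]$profile <- -mods[[p[1]]]$profile
  }
  membership <- list()
  genes <- character()
  for (nm in names(mods)) {
    ids <- sprintf("%s_%02d", toupper(nm), seq_len(mods[[nm]]$size))
    membership[[nm]] <- ids
    genes <- c(genes, ids)
  }
  sat <- list()
  for (cc in cfg$cooperative) {
    ids <- sprintf("SAT_%s_%02d", toupper(cc$module), seq_len(cc$n))
    sat[[length(sat) + 1]] <- data.frame(gene = ids, module = cc$module,
                                         strength = cc$strength, sd = cc$sd,
                                         stringsAsFactors = FALSE)
    genes <- c(genes, ids)
  }
  satellites <- if (length(sat)) do.call(rbind, sat) else
    data.frame(gene = character(), module = character(), strength = numeric(),
               sd = numeric())
  bg <- sprintf("BG_%03d", seq_len(cfg$n_background))
  kin <- names(cfg$phospho$kinases %||% list())
  genes <- c(genes, bg, kin)
  if (anyDuplicated(genes)) stopf("generated feature IDs collide")
  list(mods = mods, membership = membership, satellites = satellites,
       background = bg, kinases = kin, genes = genes)
}

#' Generate a synthetic raw-scale proteome with ground truth
#'
#' Module members share their module's log2 stage profile (repeated across
#' replicates and groups) plus a per-gene intercept and per-sample noise;
#' anticorrelated module pairs use negated profiles; cooperative satellites
#' use the module profile scaled by their correlation strength plus extra
#' independent noise; background genes get independent, noise-dominated
#' per-group stage profiles; kinase genes (when a phospho layer is
#' configured) get their activity profile as protein abundance. Raw scale is
#' `2^(log2 value + per-gene base)` with base ~ Uniform(10, 20) log2 units.
#' Fully reproducible from `config$seed`.
#'
#' @param config [synthetic_config()]
#' @return list with `matrix` (raw [abundance_matrix()]) and `truth`
#'   (module membership, satellite table, true stage profiles
#'   `[gene, stage, group]`, realized log2 values, planted discordance).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)
  layout <- build_truth_profiles(cfg)
  genes <- layout$genes
  groups <- group_names(cfg)
  P <- array(0, dim = c(length(genes), cfg$n_stages, cfg$n_groups),
             dimnames = list(genes, cfg$stages, groups))
  for (nm in names(layout$membership)) {
    for (g in layout$membership[[nm]]) {
      P[g, , ] <- layout$mods[[nm]]$profile
    }
  }
  if (nrow(layout$satellites)) {
    for (i in seq_len(nrow(layout$satellites))) {
      s <- layout$satellites[i, ]
      P[s$gene, , ] <- s$strength * layout$mods[[s$module]]$profile
    }
  }
  for (g in layout$background) {
    P[g, , ] <- matrix(stats::rnorm(cfg$n_stages * cfg$n_groups, 0,
                                    cfg$background_profile_sd),
                       cfg$n_stages, cfg$n_groups)
  }
  for (k in layout$kinases) {
    P[k, , ] <- cfg$phospho$kinases[[k]]$activity
  }
  # per-gene intercepts (module members only carry a module-sd intercept)
  intercept <- stats::setNames(numeric(length(genes)), genes)
  for (nm in names(layout$membership)) {
    ids <- layout$membership[[nm]]
    intercept[ids] <- stats::rnorm(length(ids), 0, layout$mods[[nm]]$sd)
  }
  noise_sd <- stats::setNames(rep(cfg$replicate_sd, length(genes)), genes)
  if (nrow(layout$satellites)) {
    noise_sd[layout$satellites$gene] <-
      sqrt(cfg$replicate_sd^2 + layout$satellites$sd^2)
  }
  sheet <- sample_sheet_for(cfg, "protein", cfg$n_replicates, "prot")
  log2v <- matrix(0, length(genes), nrow(sheet),
                  dimnames = list(genes, sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    s <- as.character(sheet$stage[j]); gline <- sheet$cell_line[j]
    log2v[, j] <- P[, s, gline] + intercept +
      stats::rnorm(length(genes), 0, noise_sd)
  }
  base <- stats::setNames(stats::runif(length(genes), 10, 20), genes)
  raw <- 2^(log2v + base)
  truth <- list(membership = layout$membership,
                satellites = layout$satellites,
                background = layout$background,
                kinases = layout$kinases,
                profiles = P,
                intercepts = intercept,
                protein_log2 = log2v,
                base = base,
                config = cfg)
  off <- cfg$discordance_offsets
  if (!is.null(off)) {
    offm <- do.call(rbind, off)
    rownames(offm) <- names(off)
    colnames(offm) <- cfg$stages
    truth$discordance_offsets <- offm
    # under a geometric-mean baseline only the stage-centred part of a
    # per-gene offset vector is identifiable (per-gene D sums to 0)
    truth$discordance_geomean <- offm - rowMeans(offm)
  }
  list(matrix = abundance_matrix(raw, sheet, scale = "raw"), truth = truth)
}

#' Generate the matched synthetic transcriptome
#'
#' Per gene, the RNA log2 stage profile is `concordance x` the true protein
#' profile minus the planted discordance offset, plus per-sample noise, so
#' the realized discordance statistic (protein minus RNA log2 fold change)
#' has expectation equal to the configured offset (its stage-centred part
#' under the default geometric-mean baseline). RNA uses fewer replicates than
#' protein by default.
#'
#' @param config [synthetic_config()]
#' @param truth the `truth` element returned by [generate_proteome()] for the
#'   same config.
#' @return raw-scale [abundance_matrix()] with assay `"rna"`.
#' @export
generate_transcriptome <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed + 1L)
  genes <- rownames(truth$protein_log2)
  conc <- cfg$rna_concordance
  if (is.null(names(conc))) {
    conc <- stats::setNames(rep_len(conc, length(genes)), genes)
  } else {
    full <- stats::setNames(rep(1, length(genes)), genes)
    full[names(conc)] <- conc
    conc <- full
  }
  offm <- matrix(0, length(genes), cfg$n_stages,
                 dimnames = list(genes, cfg$stages))
  if (!is.null(truth$discordance_offsets)) {
    found <- intersect(rownames(truth$discordance_offsets), genes)
    offm[found, ] <- truth$discordance_offsets[found, ]
  }
  sheet <- sample_sheet_for(cfg, "rna", cfg$rna_replicates, "rna")
  log2v <- matrix(0, length(genes), nrow(sheet),
                  dimnames = list(genes, sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    s <- as.character(sheet$stage[j]); gline <- sheet$cell_line[j]
    log2v[, j] <- conc * truth$profiles[, s, gline] - offm[, s] +
      stats::rnorm(length(genes), 0, cfg$rna_sd)
  }
  base <- stats::runif(length(genes), 6, 14)
  abundance_matrix(2^(log2v + base), sheet, scale = "raw")
}

#' Generate the matched synthetic phosphoproteome
#'
#' Each kinase in the config drives `n_sites` phosphosites placed on
#' background host proteins: a site's log2 value per sample is the host's
#' realized protein log2 value in that sample, plus the kinase activity at
#' the sample's stage, plus site noise — so subtracting the host protein
#' recovers the kinase program exactly in the noiseless limit. Additional
#' unregulated background sites carry host abundance plus noise only.
#'
#' @param config [synthetic_config()]
#' @param truth the `truth` element from [generate_proteome()].
#' @return list with `matrix` (raw [phosphosite_matrix()]), `ks_map`
#'   (data.frame kinase/substrate/site/site_id) and `activities` (kinase x
#'   stage matrix).
#' @export
generate_phosphoproteome <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  if (is.null(cfg$phospho)) stopf("config has no phospho layer")
  set.seed(cfg$seed + 2L)
  kin <- cfg$phospho$kinases
  hosts_pool <- truth$background
  n_needed <- sum(vapply(kin, `[[`, numeric(1), "n_sites")) +
    cfg$phospho$n_background_sites
  hosts <- sample(hosts_pool, n_needed, replace = n_needed > length(hosts_pool))
  residues <- sample(c("S", "T", "Y"), n_needed, replace = TRUE,
                     prob = c(0.8, 0.15, 0.05))
  positions <- sample(50:999, n_needed, replace = FALSE)
  idx <- 0
  site_rows <- list(); ks_rows <- list()
  site_log2 <- list()
  psheet <- sample_sheet_for(cfg, "phosphosite", cfg$n_replicates, "phos")
  stage_j <- as.character(psheet$stage)
  for (knm in names(kin)) {
    k <- kin[[knm]]
    for (i in seq_len(k$n_sites)) {
      idx <- idx + 1
      host <- hosts[idx]
      sid <- sprintf("%s_%s%d", host, residues[idx], positions[idx])
      site_rows[[idx]] <- data.frame(site_id = sid, protein = host,
                                     residue = residues[idx],
                                     position = positions[idx],
                                     stringsAsFactors = FALSE)
      ks_rows[[length(ks_rows) + 1]] <-
        data.frame(kinase = knm, substrate = host,
                   site = sprintf("%s%d", residues[idx], positions[idx]),
                   site_id = sid, stringsAsFactors = FALSE)
      # protein and phospho sheets share the group x stage x replicate layout,
      # so columns align positionally
      site_log2[[idx]] <- truth$protein_log2[host, ] +
        k$activity[match(stage_j, cfg$stages)] +
        stats::rnorm(nrow(psheet), 0, cfg$phospho$site_sd)
    }
  }
  for (i in seq_len(cfg$phospho$n_background_sites)) {
    idx <- idx + 1
    host <- hosts[idx]
    sid <- sprintf("%s_%s%d", host, residues[idx], positions[idx])
    site_rows[[idx]] <- data.frame(site_id = sid, protein = host,
                                   residue = residues[idx],
                                   position = positions[idx],
                                   stringsAsFactors = FALSE)
    site_log2[[idx]] <- truth$protein_log2[host, ] +
      stats::rnorm(nrow(psheet), 0, cfg$phospho$site_sd)
  }
  sites <- do.call(rbind, site_rows)
  vals <- do.call(rbind, site_log2)
  rownames(vals) <- sites$site_id
  colnames(vals) <- psheet$sample_id
  base <- stats::runif(nrow(vals), 8, 16)
  ks_map <- do.call(rbind, ks_rows)
  activities <- t(vapply(kin, `[[`, numeric(cfg$n_stages), "activity"))
  colnames(activities) <- cfg$stages
  list(matrix = phosphosite_matrix(2^(vals + base), sites, psheet, scale = "raw"),
       ks_map = ks_map, activities = activities)
}

#' Run the full synthetic generator
#'
#' Convenience wrapper calling [generate_proteome()],
#' [generate_transcriptome()] and (when configured)
#' [generate_phosphoproteome()] in order.
#'
#' @param config [synthetic_config()]
#' @return list with `proteome`, `transcriptome`, `phospho` (or `NULL`),
#'   `truth`, `config`.
#' @export
simulate_experiment <- function(config = synthetic_config()) {
  prot <- generate_proteome(config)
  rna <- generate_transcriptome(config, prot$truth)
  ph <- if (!is.null(config$phospho)) generate_phosphoproteome(config, prot$truth)
  list(proteome = prot$matrix, transcriptome = rna, phospho = ph,
       truth = prot$truth, config = config)
}

#' Gene sets of the planted modules
#'
#' Exports the simulator's module membership (members only, satellites
#' excluded) as a [gene_set_collection()] with source `complex`, for use as
#' the known-complex collection in downstream recovery analyses.
#'
#' @param truth the `truth` element from [generate_proteome()].
#' @return [gene_set_collection()]
#' @export
truth_gene_sets <- function(truth) {
  gene_set_collection(truth$membership, source = "complex")
}
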