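#!/usr/bin/env Rscript
# Generate the synthetic multi-omics experiment used by every later step:
# a stage-structured proteome with two anticorrelated co-regulated modules
# and one cooperative satellite each, a matched transcriptome with planted
# discordance offsets, and a phosphoproteome driven by one active kinase.
# Writes the raw matrices, sample sheets, planted-module GMT, the
# kinase-substrate table and the ground-truth bundle.

suppressPackageStartupMessages(library(coregulomics))

out <- file.path("results", "synthetic")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(seed = 1)
sim <- simulate_experiment(cfg)

write_abundance_matrix(sim$proteome, file.path(out, "proteome_raw.tsv"),
                       file.path(out, "proteome_samples.tsv"))
write_abundance_matrix(sim$transcriptome, file.path(out, "transcriptome_raw.tsv"),
                       file.path(out, "transcriptome_samples.tsv"))
write_abundance_matrix(sim$phospho$matrix, file.path(out, "phosphosites_raw.tsv"),
                       file.path(out, "phosphosite_samples.tsv"))
write_gmt(truth_gene_sets(sim$truth), file.path(out, "planted_modules.gmt"))
write.table(sim$phospho$ks_map[c("kinase", "substrate", "site")],
            file.path(out, "kinase_substrates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

membership <- do.call(rbind, lapply(names(sim$truth$membership), function(m) {
  data.frame(gene = sim$truth$membership[[m]], module = m)
}))
write.table(membership, file.path(out, "truth_membership.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene = rownames(sim$truth$discordance_geomean),
                       sim$truth$discordance_geomean, check.names = FALSE),
            file.path(out, "truth_discordance_offsets.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("proteome: %d genes x %d samples; RNA: %d samples; sites: %d x %d\n",
            nrow(sim$proteome$values), ncol(sim$proteome$values),
            ncol(sim$transcriptome$values),
            nrow(sim$phospho$matrix$values), ncol(sim$phospho$matrix$values)))
cat(sprintf("planted: %d module genes, %d satellites, %d genes with discordance offsets, %d kinases\n",
            nrow(membership), nrow(sim$truth$satellites),
            nrow(sim$truth$discordance_geomean),
            length(sim$truth$kinases)))
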