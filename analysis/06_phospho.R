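#!/usr/bin/env Rscript
# Phosphosite analysis: protein-subtracted site ratios, KSEA kinase activity
# z-scores with the >= 2 substrate cutoff, the |r| >= 0.5 kinase-substrate
# correlation network, and site-host correlation descriptives.

suppressPackageStartupMessages(library(coregulomics))

out <- file.path("results", "phospho")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

syn <- file.path("results", "synthetic")
prot <- normalize_to_geometric_mean(
  read_abundance_matrix(file.path(syn, "proteome_raw.tsv"),
                        file.path(syn, "proteome_samples.tsv")))
sites <- normalize_to_geometric_mean(
  read_phosphosite_matrix(file.path(syn, "phosphosites_raw.tsv"),
                          file.path(syn, "phosphosite_samples.tsv")))
ks <- read_ks_map(file.path(syn, "kinase_substrates.tsv"))

spc <- site_protein_correlation(sites, prot)
cat(sprintf("median site-host correlation before protein subtraction: r = %.2f\n",
            spc$median_r))

sub <- protein_normalize_sites(sites, prot)
write_abundance_matrix(sub, file.path(out, "sites_protein_subtracted.tsv"))

kz <- ksea_zscores(sub, ks, min_substrates = 2)
write.table(data.frame(kinase = rownames(kz$z), kz$z, check.names = FALSE),
            file.path(out, "ksea_zscores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
peak <- sort(apply(abs(kz$z), 1, max), decreasing = TRUE)
cat("peak |KSEA z| per kinase:",
    paste(sprintf("%s = %.2f", names(peak), peak), collapse = ", "), "\n")

net <- kinase_substrate_network(prot, sub, ks, r_min = 0.5)
write.table(net, file.path(out, "kinase_substrate_network.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("kinase-substrate network: %d pairs at |r| >= 0.5 (%d positive)\n",
            nrow(net), sum(net$sign == "positive")))
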