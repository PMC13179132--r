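paired_fixture <- function(rna_fun = identity, n_genes = 5, seed = 81) {
  set.seed(seed)
  stages <- rep(c("s1", "s2", "s3"), each = 2)
  pv <- matrix(rnorm(n_genes * 6), n_genes, 6,
               dimnames = list(sprintf("G%02d", seq_len(n_genes)), NULL))
  pv <- pv - rowMeans(pv)
  rv <- rna_fun(pv)
  list(protein = toy_matrix(pv, stages = stages, assay = "protein"),
       rna = toy_matrix(rv, stages = stages, assay = "rna"))
}

test_that("per-gene RNA-protein correlation hits the exact limits", {
  fx <- paired_fixture()
  res <- per_gene_rna_protein_correlation(fx$protein, fx$rna)
  expect_equal(res$per_gene$r, rep(1, 5), tolerance = 1e-12)
  neg <- per_gene_rna_protein_correlation(fx$protein,
                                          paired_fixture(function(x) -x)$rna)
  expect_equal(neg$per_gene$r, rep(-1, 5), tolerance = 1e-12)
})

test_that("per-gene correlation matches the naive formula on a toy set", {
  fx1 <- paired_fixture(seed = 82)
  fx2 <- paired_fixture(seed = 83)  # unrelated RNA
  res <- per_gene_rna_protein_correlation(fx1$protein, fx2$rna)
  pm <- sapply(c("s1", "s2", "s3"), function(s)
    rowMeans(fx1$protein$values[, rep(c("s1", "s2", "s3"), each = 2) == s]))
  rm_ <- sapply(c("s1", "s2", "s3"), function(s)
    rowMeans(fx2$rna$values[, rep(c("s1", "s2", "s3"), each = 2) == s]))
  for (g in res$per_gene$gene) {
    expect_equal(res$per_gene$r[res$per_gene$gene == g],
                 naive_pearson(pm[g, ], rm_[g, ]), tolerance = 1e-12)
  }
})

test_that("per-gene correlation requires at least 3 paired conditions", {
  pv <- matrix(rnorm(4), 2, 2, dimnames = list(c("a", "b"), NULL))
  p <- toy_matrix(pv, stages = c("s1", "s2"))
  r <- toy_matrix(pv, stages = c("s1", "s2"), assay = "rna")
  expect_error(per_gene_rna_protein_correlation(p, r), "3 paired")
})

test_that("discordance classifies against the log2 threshold", {
  pv <- rbind(conc = c(1.7, 1.7, 0, 0, -1.7, -1.7),
              protab = c(2, 2, 0, 0, -2, -2),
              rnaab = c(0, 0, 0, 0, 0, 0))
  rv <- rbind(conc = c(1.7, 1.7, 0, 0, -1.7, -1.7),
              protab = c(0, 0, 0, 0, 0, 0),
              rnaab = c(2, 2, 0, 0, -2, -2))
  stages <- rep(c("s1", "s2", "s3"), each = 2)
  disc <- compute_discordance(toy_matrix(pv, stages = stages),
                              toy_matrix(rv, stages = stages, assay = "rna"))
  rec <- disc$records
  expect_equal(rec$discordance[rec$gene == "conc"], rep(0, 3))
  expect_true(all(rec$class[rec$gene == "conc"] == "concordant"))
  s1 <- rec[rec$stage == "s1", ]
  expect_equal(s1$discordance[s1$gene == "protab"], 2)
  expect_identical(s1$class[s1$gene == "protab"], "protein_abundant")
  expect_equal(s1$discordance[s1$gene == "rnaab"], -2)
  expect_identical(s1$class[s1$gene == "rnaab"], "rna_abundant")
})

test_that("discordance is antisymmetric under swapping the assays", {
  fx <- paired_fixture(function(x) x + matrix(rnorm(length(x)), nrow(x)))
  d1 <- compute_discordance(fx$protein, fx$rna)$records
  d2 <- compute_discordance(fx$rna, fx$protein)$records
  expect_equal(d1$discordance, -d2$discordance)
})

test_that("genes present in one assay are skipped and counted", {
  fx <- paired_fixture()
  rna2 <- fx$rna
  rna2$values <- rna2$values[-1, ]
  rna2 <- abundance_matrix(rna2$values, rna2$samples, scale = "log2_ratio")
  disc <- compute_discordance(fx$protein, rna2)
  expect_equal(disc$coverage$n_shared, 4)
  expect_equal(disc$coverage$n_skipped, 1)
  expect_false("G01" %in% disc$records$gene)
})

test_that("planted offsets are recovered with small error under noise", {
  cfg <- synthetic_config(seed = 19)
  # 100 genes carrying a +2 early-stage offset, noise sd 0.1
  cfg$n_background <- 120
  cfg$discordance_offsets <- stats::setNames(
    replicate(100, c(0, 2, 0), simplify = FALSE), sprintf("BG_%03d", 1:100))
  sim <- simulate_experiment(cfg)
  pn <- normalize_to_geometric_mean(sim$proteome)
  rn <- normalize_to_geometric_mean(sim$transcriptome)
  rec <- compute_discordance(pn, rn)$records
  tg <- sim$truth$discordance_geomean
  err <- vapply(rownames(tg), function(g) {
    est <- rec$discordance[rec$gene == g][match(colnames(tg), rec$stage[rec$gene == g])]
    est - tg[g, ]
  }, numeric(ncol(tg)))
  expect_lt(sqrt(mean(err^2)), 0.3)
  expect_lt(abs(mean(err)), 0.05)
})

test_that("complex summaries take medians over detected members only", {
  per_gene_r <- data.frame(gene = c("a", "b", "c", "d"), r = c(0.1, 0.5, 0.9, 0.2))
  records <- data.frame(gene = rep(c("a", "b", "c", "d"), each = 2),
                        stage = rep(c("s1", "s2"), 4),
                        protein_fc = 0, rna_fc = 0,
                        discordance = c(1, 0, 2, 0, 3, 0, 4, 0),
                        class = "concordant")
  gsc <- gene_set_collection(list(trio = c("a", "b", "c"), duo = c("a", "b")),
                             "complex")
  out <- complex_discordance_summary(per_gene_r, records, gsc)
  expect_equal(out$complex, "trio")  # 2-member complex excluded
  expect_equal(out$median_r, 0.5)
  expect_equal(out$median_D_s1, 2)

  # medians agree with a sort-based oracle on random member sets
  set.seed(91)
  genes <- sprintf("g%02d", 1:20)
  pg <- data.frame(gene = genes, r = runif(20, -1, 1))
  rcd <- data.frame(gene = genes, stage = "s1", protein_fc = 0, rna_fc = 0,
                    discordance = rnorm(20), class = "concordant")
  for (i in 1:5) {
    mem <- sample(genes, sample(3:8, 1))
    g2 <- gene_set_collection(list(s = mem), "complex")
    out2 <- complex_discordance_summary(pg, rcd, g2)
    sorted <- sort(pg$r[pg$gene %in% mem])
    n <- length(sorted)
    want <- if (n %% 2) sorted[(n + 1) / 2] else mean(sorted[n / 2 + 0:1])
    expect_equal(out2$median_r, want, tolerance = 1e-12)
  }
})

test_that("stage-transition test detects a complex-wide planted offset", {
  set.seed(101)
  stages <- rep(c("s1", "s2", "s3"), each = 2)
  members <- sprintf("m%d", 1:8)
  base <- matrix(rnorm(8 * 6, 0, 0.5), 8, 6, dimnames = list(members, NULL))
  pv <- base
  # protein gains 2 log2 units at s3 relative to RNA, member noise 0.05
  pv[, stages == "s3"] <- pv[, stages == "s3"] + 2 +
    rnorm(sum(stages == "s3") * 8, 0, 0.05)
  p <- toy_matrix(pv, stages = stages)
  r <- toy_matrix(base, stages = stages, assay = "rna")
  gsc <- gene_set_collection(list(cx = members), "complex")
  res <- stage_transition_discordance_test(p, r, gsc, "s1", "s3")
  expect_lt(res$p_adj, 0.05)
  expect_equal(res$mean_diff, 2, tolerance = 0.2)

  # identical fold changes sit in the p = 1 region
  same <- stage_transition_discordance_test(p, p, gsc, "s1", "s3")
  expect_equal(same$p_raw, 1)

  # antisymmetry: swapping assays flips the mean difference, p unchanged
  swap <- stage_transition_discordance_test(r, p, gsc, "s1", "s3")
  expect_equal(swap$mean_diff, -res$mean_diff)
  expect_equal(swap$p_raw, res$p_raw)
})

test_that("stage-transition test controls its type-I error at the null", {
  set.seed(111)
  stages <- rep(c("s1", "s2"), each = 2)
  hits <- replicate(1000, {
    pv <- matrix(rnorm(6 * 4, 0, 0.3), 6, 4, dimnames = list(sprintf("m%d", 1:6), NULL))
    rv <- pv + matrix(rnorm(24, 0, 0.3), 6, 4)
    p <- toy_matrix(pv, stages = stages)
    r <- toy_matrix(rv, stages = stages, assay = "rna")
    gsc <- gene_set_collection(list(cx = rownames(pv)), "complex")
    stage_transition_discordance_test(p, r, gsc, "s1", "s2")$p_raw < 0.05
  })
  expect_lte(mean(hits), 0.06)
})

test_that("TF-target retrieval keeps only tracking targets with their peak stage", {
  stages <- rep(c("s1", "s2", "s3"), each = 2)
  tf_prof <- c(0, 0, 1, 1, 2, 2)
  pv <- rbind(TF1 = tf_prof)
  rv <- rbind(t_track = tf_prof + rnorm(6, 0, 1e-6),
              t_flat = rep(0, 6),
              t_anti = -tf_prof)
  p <- toy_matrix(pv, stages = stages)
  r <- toy_matrix(rv, stages = stages, assay = "rna")
  res <- tf_target_concordance("TF1", p, r, targets = c("t_track", "t_flat", "t_anti"))
  expect_equal(res$targets$gene, "t_track")
  expect_identical(res$targets$argmax_stage, "s3")
  expect_identical(res$tf_argmax_stage, "s3")
  expect_error(tf_target_concordance("NOPE", p, r, "t_track"), "absent")

  # brute-force filter agreement
  keep <- vapply(rownames(rv), function(g) {
    rr <- suppressWarnings(naive_pearson(
      tapply(rv[g, ], stages, mean)[c("s1", "s2", "s3")],
      tapply(tf_prof, stages, mean)[c("s1", "s2", "s3")]))
    !is.na(rr) && rr >= 0.9
  }, logical(1))
  expect_setequal(res$targets$gene, rownames(rv)[keep])
})
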