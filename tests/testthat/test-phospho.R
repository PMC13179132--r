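phospho_fixture <- function() {
  stages <- rep(c("s1", "s2", "s3"), each = 2)
  prot <- toy_matrix(rbind(HOST = c(1, 1, 1, 1, 1, 1),
                           OTHER = c(0, 0, 1, 1, 2, 2)),
                     stages = stages)
  sv <- rbind(HOST_S10 = c(1, 2, 3, 1, 2, 3),
              HOST_T20 = c(1, 1, 1, 1, 1, 1),
              GHOST_S5 = c(0, 1, 0, 1, 0, 1))
  sites <- parse_site_ids(rownames(sv))
  pm <- phosphosite_matrix(sv, sites, prot$samples, scale = "log2_ratio")
  list(prot = prot, pm = pm)
}

test_that("protein subtraction is elementwise and flags unquantified hosts", {
  fx <- phospho_fixture()
  out <- protein_normalize_sites(fx$pm, fx$prot)
  expect_equal(unname(out$values["HOST_S10", ]), c(0, 1, 2, 0, 1, 2))
  expect_equal(unname(out$values["HOST_T20", ]), rep(0, 6))
  # GHOST has no protein row: retained unnormalized, flagged
  expect_equal(out$values["GHOST_S5", ], fx$pm$values["GHOST_S5", ])
  expect_identical(out$sites$normalized[out$sites$site_id == "GHOST_S5"], FALSE)
  # adding the protein back reproduces the input exactly
  back <- out$values
  back[out$sites$normalized, ] <- back[out$sites$normalized, , drop = FALSE] +
    fx$prot$values[out$sites$protein[out$sites$normalized], ]
  expect_equal(back, fx$pm$values)
})

test_that("sample-axis mismatch between sites and proteins is an error", {
  fx <- phospho_fixture()
  prot2 <- fx$prot
  prot2$samples$replicate <- prot2$samples$replicate + 10
  expect_error(protein_normalize_sites(fx$pm, prot2), "align")
})

test_that("KSEA z matches the direct formula", {
  # sites {0,0,0,0,1,1} in one sample; kinase owns the two 1-valued sites
  sv <- matrix(c(0, 0, 0, 0, 1, 1), 6, 3,
               dimnames = list(sprintf("P%d_S%d", 1:6, 1:6), NULL))
  # row-mean centring must not disturb the example: make rows mean-zero by
  # mirroring the values across samples
  sv[, 2] <- -sv[, 1]; sv[, 3] <- 0
  sites <- parse_site_ids(rownames(sv))
  sheet <- data.frame(sample_id = paste0("c", 1:3), species = "synthetic",
                      cell_line = "x", stage = factor(c("s1", "s2", "s3"), ordered = TRUE),
                      replicate = 1, assay = "phosphosite")
  colnames(sv) <- sheet$sample_id
  pm <- phosphosite_matrix(sv, sites, sheet, scale = "log2_ratio")
  ks <- data.frame(kinase = "K", site_id = c("P5_S5", "P6_S6"))
  z <- ksea_zscores(pm, ks)
  want <- ((1 - 1 / 3) * sqrt(2)) / sd(c(0, 0, 0, 0, 1, 1))
  expect_equal(unname(z$z["K", "c1"]), want, tolerance = 1e-12)
  expect_equal(unname(z$z["K", "c2"]), -want, tolerance = 1e-12)
  expect_equal(unname(z$n_substrates["K"]), 2L)
})

test_that("KSEA omits kinases below the substrate cutoff", {
  fx <- phospho_fixture()
  sub <- protein_normalize_sites(fx$pm, fx$prot)
  ks <- data.frame(kinase = c("K1", "K1", "K2"),
                   site_id = c("HOST_S10", "HOST_T20", "GHOST_S5"))
  z <- ksea_zscores(sub, ks, min_substrates = 2)
  expect_setequal(rownames(z$z), "K1")
  z1 <- ksea_zscores(sub, ks, min_substrates = 1)
  expect_setequal(rownames(z1$z), c("K1", "K2"))
  empty <- phosphosite_matrix(matrix(numeric(), 0, 6,
                                     dimnames = list(character(0), fx$prot$samples$sample_id)),
                              data.frame(site_id = character(), protein = character(),
                                         residue = character(), position = integer()),
                              fx$prot$samples, scale = "log2_ratio")
  expect_error(ksea_zscores(empty, ks), "empty")
})

test_that("KSEA is invariant to a constant shift of all site values", {
  fx <- phospho_fixture()
  sub <- protein_normalize_sites(fx$pm, fx$prot)
  ks <- data.frame(kinase = "K1", site_id = c("HOST_S10", "HOST_T20"))
  z1 <- ksea_zscores(sub, ks)
  shifted <- phosphosite_matrix(sub$values + 7, sub$sites[names(sub$sites) != "normalized"],
                                sub$samples, scale = "log2_ratio")
  z2 <- ksea_zscores(shifted, ks)
  expect_equal(z1$z, z2$z, tolerance = 1e-12)
})

test_that("kinase-substrate network applies the |r| gate with signs", {
  stages <- rep(c("s1", "s2", "s3"), each = 2)
  kin <- toy_matrix(rbind(KIN = c(0, 0, 1, 1, 2, 2)), stages = stages)
  sv <- rbind(A_S1 = c(0, 0, 1, 1, 2, 2),       # r = 1
              B_S2 = c(2, 2, 1, 1, 0, 0),       # r = -1
              C_S3 = c(0, 1, 0, 1, 0, 1),       # |r| < 0.5
              D_S4 = rep(1, 6))                  # constant: dropped
  pm <- phosphosite_matrix(sv, parse_site_ids(rownames(sv)), kin$samples,
                           scale = "log2_ratio")
  ks <- data.frame(kinase = "KIN", site_id = rownames(sv))
  net <- kinase_substrate_network(kin, pm, ks, r_min = 0.5)
  expect_setequal(net$site_id, c("A_S1", "B_S2"))
  expect_equal(net$sign[net$site_id == "A_S1"], "positive")
  expect_equal(net$sign[net$site_id == "B_S2"], "negative")
  # brute-force per-pair oracle
  for (k in seq_len(nrow(net))) {
    expect_equal(net$r[k], naive_pearson(kin$values["KIN", ], sv[net$site_id[k], ]),
                 tolerance = 1e-12)
  }
  # a pair at |r| just under the gate is excluded
  expect_false("C_S3" %in% net$site_id)
})

test_that("site-protein correlation summarizes with a sort-based median", {
  stages <- rep(c("s1", "s2", "s3"), each = 2)
  prot <- toy_matrix(rbind(H1 = c(0, 0, 1, 1, 2, 2),
                           H2 = c(1, 0, 0, 1, 1, 0)), stages = stages)
  sv <- rbind(H1_S1 = c(0, 0, 1, 1, 2, 2),          # r = 1 with host
              H2_S2 = c(0, 1, 1, 0, 0, 1),          # r = -1 with host
              H1_T3 = c(1, -1, 1, -1, 1, -1))
  pm <- phosphosite_matrix(sv, parse_site_ids(rownames(sv)), prot$samples,
                           scale = "log2_ratio")
  res <- site_protein_correlation(pm, prot)
  expect_equal(res$per_site$r[res$per_site$site_id == "H1_S1"], 1, tolerance = 1e-12)
  rs <- sort(res$per_site$r)
  expect_equal(res$median_r, rs[(length(rs) + 1) / 2])
})

test_that("duplicate phosphopeptides collapse to the per-sample median", {
  stages <- c("s1", "s2", "s3")
  sheet <- data.frame(sample_id = paste0("c", 1:3), species = "synthetic",
                      cell_line = "x", stage = factor(stages, ordered = TRUE),
                      replicate = 1, assay = "phosphosite")
  v <- rbind(c(1, 2, 3), c(3, 4, 5), c(0, 0, 100))
  rownames(v) <- rep("H_S9", 3)
  colnames(v) <- sheet$sample_id
  sites <- parse_site_ids(rownames(v))
  out <- collapse_phosphopeptides(v, sites, sheet, scale = "log2_ratio")
  expect_equal(nrow(out$values), 1)
  expect_equal(unname(out$values[1, ]), c(1, 2, 5))
})

test_that("site identity parsing and validation reject malformed records", {
  parsed <- parse_site_ids(c("UTF1_T35", "H2AX_S140"))
  expect_equal(parsed$protein, c("UTF1", "H2AX"))
  expect_equal(parsed$position, c(35L, 140L))
  expect_error(parse_site_ids("UTF1-35"), "malformed")
  fx <- phospho_fixture()
  dup_sites <- rbind(fx$pm$sites, fx$pm$sites[1, ])
  expect_error(phosphosite_matrix(rbind(fx$pm$values, X = fx$pm$values[1, ]),
                                  dup_sites, fx$prot$samples,
                                  scale = "log2_ratio"),
               "duplicate")
})
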