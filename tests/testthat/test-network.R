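test_that("the pair universe counts match the closed form", {
  expect_equal(count_feature_pairs(4), 6)
  expect_equal(count_feature_pairs(letters[1:5]), choose(5, 2))
  expect_equal(count_feature_pairs(100), choose(100, 2))
})

test_that("blocked all-pairs correlations match the naive per-pair formula", {
  set.seed(21)
  v <- matrix(rnorm(6 * 8), 6, 8, dimnames = list(paste0("P", 1:6), NULL))
  am <- toy_matrix(v, stages = rep(c("s1", "s2"), each = 4))
  for (bs in c(2, 512)) {  # multiple blocks and a single block agree
    pairs <- pairwise_correlations(am, block_size = bs)
    expect_equal(nrow(pairs), choose(6, 2))
    for (k in seq_len(nrow(pairs))) {
      want <- naive_pearson(v[pairs$protein_a[k], ], v[pairs$protein_b[k], ])
      expect_equal(pairs$r[k], want, tolerance = 1e-12)
    }
  }
})

test_that("duplicated features correlate at r = 1 and constants are undefined", {
  v <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(5, 5, 5, 5))
  am <- toy_matrix(v, stages = c("s1", "s1", "s2", "s2"))
  pairs <- pairwise_correlations(am)
  ab <- pairs[pairs$protein_a == "a" & pairs$protein_b == "b", ]
  expect_equal(ab$r, 1)
  expect_equal(ab$p_raw, 0)
  expect_true(all(is.na(pairs$r[pairs$protein_a == "c" | pairs$protein_b == "c"])))
})

test_that("the permutation null is seeded, centred and caps its pair draw", {
  set.seed(31)
  v <- matrix(rnorm(30 * 12), 30, 12, dimnames = list(paste0("P", 1:30), NULL))
  am <- toy_matrix(v, stages = rep(c("s1", "s2", "s3"), each = 4))
  n1 <- permutation_null(am, n_pairs = 400, n_shuffles = 5, seed = 9)
  n2 <- permutation_null(am, n_pairs = 400, n_shuffles = 5, seed = 9)
  expect_identical(n1$r, n2$r)
  expect_length(n1$r, 2000 - n1$n_dropped)
  # CLT bound on the null mean
  expect_lt(abs(mean(n1$r)), 3 * sd(n1$r) / sqrt(length(n1$r)))
  expect_warning(permutation_null(am, n_pairs = 1e6, n_shuffles = 1, seed = 1),
                 "capped")
})

test_that("the permutation null drops all pairs for constant data", {
  v <- matrix(5, 4, 6, dimnames = list(paste0("P", 1:4), NULL))
  am <- toy_matrix(v, stages = rep(c("s1", "s2"), each = 3))
  null <- permutation_null(am, n_pairs = 3, n_shuffles = 2, seed = 1)
  expect_length(null$r, 0)
  expect_equal(null$n_dropped, 6)
})

test_that("edge filtering applies both gates with BH over the full universe", {
  pairs <- data.frame(protein_a = c("A", "A", "B"),
                      protein_b = c("B", "C", "C"),
                      r = c(0.94, 0.99, -0.97),
                      p_raw = c(1e-10, 1e-8, 1e-6))
  net <- build_network(pairs, r_min = 0.95, alpha = 0.01)
  expect_equal(nrow(net$edges), 2)  # r = 0.94 excluded despite its tiny p
  expect_false(any(net$edges$r == 0.94))
  expect_equal(sort(net$edges$sign), c("negative", "positive"))
  # oracle: brute-force filter over the same table
  p_adj <- bh_stepup(pairs$p_raw)
  want <- pairs[abs(pairs$r) >= 0.95 & p_adj < 0.01, ]
  expect_setequal(paste(net$edges$protein_a, net$edges$protein_b),
                  paste(want$protein_a, want$protein_b))
})

test_that("a noiseless planted module yields its complete positive clique", {
  v <- matrix(rep(c(0, 1, 2, 0, 1, 2), 5), 5, 6, byrow = TRUE,
              dimnames = list(paste0("M", 1:5), NULL))
  v <- v + matrix(rnorm(30, 0, 1e-9), 5, 6)
  am <- toy_matrix(v, stages = rep(c("s1", "s2", "s3"), 2))
  net <- coregulation_network(am)
  expect_equal(nrow(net$edges), 10)
  expect_true(all(net$edges$sign == "positive"))
})

test_that("network edges are invariant under feature-row permutation", {
  set.seed(41)
  sim <- generate_proteome(synthetic_config(n_background = 10, seed = 2))
  norm <- normalize_to_geometric_mean(sim$matrix)
  net1 <- coregulation_network(norm)
  perm <- sample(nrow(norm$values))
  am2 <- abundance_matrix(norm$values[perm, ], norm$samples, scale = "log2_ratio")
  net2 <- coregulation_network(am2)
  expect_equal(net1$edges[c("protein_a", "protein_b", "r")],
               net2$edges[c("protein_a", "protein_b", "r")])
})

test_that("degree statistics satisfy hand counts and the handshake lemma", {
  tri <- toy_network(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  ds <- degree_stats(tri)
  expect_equal(ds$mean_degree, 2)
  expect_equal(ds$sd_degree, 0)

  star <- toy_network(cbind("HUB", paste0("L", 1:4)))
  ds2 <- degree_stats(star)
  expect_equal(sort(ds2$degrees$degree, decreasing = TRUE), c(4, 1, 1, 1, 1))
  expect_equal(ds2$mean_degree, 1.6)

  set.seed(5)
  for (i in 1:5) {
    n <- sample(5:12, 1)
    all_pairs <- t(combn(paste0("N", seq_len(n)), 2))
    pick <- all_pairs[sample(nrow(all_pairs), sample(3:nrow(all_pairs), 1)), , drop = FALSE]
    net <- toy_network(pick)
    ds <- degree_stats(net)
    expect_equal(sum(ds$degrees$degree), 2 * nrow(net$edges))
  }

  empty <- correlation_network(data.frame(protein_a = character(), protein_b = character(),
                                          r = numeric(), p_raw = numeric(),
                                          p_adj = numeric(), sign = character()),
                               nodes = c("A", "B"))
  expect_warning(ds0 <- degree_stats(empty), "no edges")
  expect_equal(ds0$mean_degree, 0)
})

test_that("edge annotation agrees with an exhaustive set-intersection oracle", {
  set.seed(51)
  nodes <- paste0("P", 1:10)
  all_pairs <- t(combn(nodes, 2))
  net <- toy_network(all_pairs[sample(45, 12), ], nodes = nodes)
  gsc <- gene_set_collection(list(c1 = sample(nodes, 4), c2 = sample(nodes, 5)),
                             "complex")
  ann <- annotate_edges(net, list(complex = gsc))
  for (k in seq_len(nrow(ann$edge_flags))) {
    a <- ann$edge_flags$protein_a[k]; b <- ann$edge_flags$protein_b[k]
    want <- any(vapply(gsc$sets, function(s) a %in% s && b %in% s, logical(1)))
    expect_identical(ann$edge_flags$complex[k], want)
  }
  # an edge between proteins sharing no set is unannotated
  lonely <- gene_set_collection(list(x = c("P1", "ZZ")), "complex")
  ann2 <- annotate_edges(net, list(complex = lonely))
  expect_false(any(ann2$edge_flags$complex))
})

test_that("annotation enrichment ratio matches hand computation", {
  nodes <- paste0("N", 1:10)
  # observed: 5 positive edges, 2 of them inside the annotated clique
  net <- toy_network(rbind(c("N1", "N2"), c("N2", "N3"), c("N4", "N5"),
                           c("N6", "N7"), c("N8", "N9")), nodes = nodes)
  gsc <- gene_set_collection(list(cl = c("N1", "N2", "N3", "N10")), "complex")
  # possible annotated pairs: C(4,2) = 6 of the 45 node pairs
  res <- annotation_enrichment_ratio(net, gsc)
  expect_equal(res$observed_fraction, 2 / 5)
  expect_equal(res$expected_fraction, 6 / 45)
  expect_equal(res$ratio, (2 / 5) / (6 / 45))

  # a category annotating every pair gives ratio 1
  all_set <- gene_set_collection(list(all = nodes), "localization")
  res2 <- annotation_enrichment_ratio(net, all_set)
  expect_equal(res2$ratio, 1)
})

test_that("edges drawn uniformly at random have enrichment ratio near 1", {
  set.seed(61)
  nodes <- paste0("R", 1:30)
  all_pairs <- t(combn(nodes, 2))
  gsc <- gene_set_collection(list(s1 = sample(nodes, 8), s2 = sample(nodes, 10)),
                             "pathway")
  ratios <- replicate(50, {
    net <- toy_network(all_pairs[sample(nrow(all_pairs), 40), ], nodes = nodes)
    annotation_enrichment_ratio(net, gsc)$ratio
  })
  expect_equal(mean(ratios), 1, tolerance = 0.1)
})

test_that("complex recovery reports hand-counted edge fractions", {
  members <- c("A", "B", "C", "D")
  net <- toy_network(t(combn(members, 2)))  # complete positive clique
  rec <- complex_recovery(net, members)
  expect_equal(rec$n_members_in_network, 4)
  expect_equal(rec$pct_possible_edges_present, 100)
  expect_equal(rec$pct_edges_positive, 100)

  part <- toy_network(rbind(c("A", "B"), c("C", "D"), c("A", "X")),
                      nodes = c(members, "X"))
  rec2 <- complex_recovery(part, members)
  expect_equal(rec2$pct_possible_edges_present, 100 * 2 / 6)

  expect_null(complex_recovery(net, c("Y", "Z")))
})

test_that("mean set correlation averages all detected pairs", {
  v <- rbind(a = c(0, 1, 2, 3), b = c(0, 1, 2, 3), c = c(3, 1, 0, 2))
  am <- toy_matrix(v, stages = c("s1", "s1", "s2", "s2"))
  expect_equal(mean_set_correlation(am, c("a", "b")), 1, tolerance = 1e-12)
  want <- mean(c(naive_pearson(v["a", ], v["b", ]),
                 naive_pearson(v["a", ], v["c", ]),
                 naive_pearson(v["b", ], v["c", ])))
  expect_equal(mean_set_correlation(am, c("a", "b", "c")), want, tolerance = 1e-12)
  expect_warning(single <- mean_set_correlation(am, "a"), "undefined")
  expect_true(is.na(single))
})
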