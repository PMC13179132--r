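# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# plain-formula Pearson correlation
naive_pearson <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# Benjamini-Hochberg step-up, written from the definition
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- pmin(rev(cummin(rev(adj))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# one-sided hypergeometric tail P(X >= ov) by exact enumeration
hyper_enum <- function(ov, K, N, n) {
  ks <- ov:min(K, n)
  sum(vapply(ks, function(k) choose(K, k) * choose(N - K, n - k), numeric(1))) /
    choose(N, n)
}

# one-sided (greater) Fisher p for a 2x2 table by enumerating all tables with
# the same margins
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(m, k)
  xs <- lo:hi
  probs <- vapply(xs, function(x) choose(m, x) * choose(n2, k - x), numeric(1))
  probs <- probs / sum(probs)
  sum(probs[xs >= a])
}

# feature x sample abundance_matrix over a stage design, from explicit values
toy_matrix <- function(values, stages = NULL, scale = "log2_ratio",
                       cell_line = "lineA", assay = "protein", prefix = "smp") {
  if (is.null(stages)) stages <- paste0("s", seq_len(ncol(values)))
  sheet <- data.frame(
    sample_id = paste0(prefix, seq_len(ncol(values))),
    species = "synthetic", cell_line = cell_line,
    stage = factor(stages, levels = unique(stages), ordered = TRUE),
    replicate = stats::ave(seq_along(stages), stages, FUN = seq_along),
    assay = assay, stringsAsFactors = FALSE)
  colnames(values) <- sheet$sample_id
  abundance_matrix(values, sheet, scale = scale)
}

# random positive raw matrix with a stage design
random_raw_matrix <- function(n_features, n_stages = 3, n_reps = 2, seed = 1) {
  set.seed(seed)
  stages <- rep(paste0("s", seq_len(n_stages)), each = n_reps)
  v <- matrix(2^stats::rnorm(n_features * length(stages), 10, 1),
              n_features, length(stages),
              dimnames = list(sprintf("F%03d", seq_len(n_features)), NULL))
  toy_matrix(v, stages = stages, scale = "raw")
}

# small correlation_network straight from explicit edges
toy_network <- function(pairs, r = 0.99, nodes = NULL) {
  e <- data.frame(protein_a = pairs[, 1], protein_b = pairs[, 2],
                  r = rep_len(r, nrow(pairs)),
                  p_raw = 1e-6, p_adj = 1e-4, sign = "positive",
                  stringsAsFactors = FALSE)
  e$sign <- ifelse(e$r > 0, "positive", "negative")
  correlation_network(e, nodes = nodes)
}
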