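# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-sided p-value for a Pearson correlation via the t transform, df = n - 2.
# r exactly +/-1 maps to p = 0.
cor_pvalue <- function(r, n) {
  df <- n - 2
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  r2 <- pmin(r[ok]^2, 1)
  tt <- abs(r[ok]) * sqrt(df / pmax(1 - r2, .Machine$double.xmin))
  p[ok] <- 2 * stats::pt(tt, df, lower.tail = FALSE)
  p[ok][r2 >= 1] <- 0
  p
}

# Canonical unordered pair ordering: lexicographic on feature IDs.
canonical_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b)
}

pair_key <- function(a, b) {
  cp <- canonical_pairs(a, b)
  paste(cp$a, cp$b, sep = "\r")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
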