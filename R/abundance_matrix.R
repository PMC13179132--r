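#' Feature-by-sample abundance matrix with sample metadata
#'
#' The common currency of the pipeline: a dense numeric matrix of feature
#' abundances (proteins, transcripts or phosphosites) with one row per feature
#' and one column per sample, a sample sheet describing each column, and a
#' `scale` tag recording whether values are raw positive intensities or
#' log2 ratios to a baseline. Missing values are explicit `NA`s, never silent
#' zeros.
#'
#' @param values numeric matrix, features in rows (rownames = feature IDs),
#'   samples in columns (colnames = sample IDs).
#' @param samples data.frame with one row per column of `values`; must contain
#'   `sample_id` matching the column names, and normally `species`,
#'   `cell_line`, `stage` (factor with ordered levels), `replicate`, `assay`.
#' @param scale `"raw"` (positive intensities) or `"log2_ratio"`.
#'
#' @return An object of class `abundance_matrix`: a list with elements
#'   `values`, `samples`, `scale`.
#' @export
abundance_matrix <- function(values, samples, scale = c("raw", "log2_ratio")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) && nrow(values) > 0) {
    stopf("values must have feature IDs as rownames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stopf("duplicate feature IDs: %s", paste(dup, collapse = ", "))
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(samples)) stopf("sample sheet must have a sample_id column")
  if (anyDuplicated(samples$sample_id)) stopf("duplicate sample_id in sample sheet")
  if (ncol(values) != nrow(samples)) {
    stopf("values has %d columns but sample sheet has %d rows", ncol(values), nrow(samples))
  }
  if (!is.null(colnames(values))) {
    missing <- setdiff(colnames(values), samples$sample_id)
    if (length(missing)) {
      stopf("samples in matrix absent from sheet: %s", paste(missing, collapse = ", "))
    }
    samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
    rownames(samples) <- NULL
  } else {
    colnames(values) <- samples$sample_id
  }
  structure(list(values = values, samples = samples, scale = scale),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d features x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  if ("assay" %in% names(x$samples)) {
    cat("assays:", paste(unique(x$samples$assay), collapse = ", "), "\n")
  }
  if ("stage" %in% names(x$samples)) {
    cat("stages:", paste(unique(as.character(x$samples$stage)), collapse = " < "), "\n")
  }
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Read an abundance matrix from a TSV file plus a sample sheet
#'
#' The matrix file is tab-separated with a single header row: first column
#' feature IDs, remaining columns sample IDs. The sample sheet is a TSV with a
#' `sample_id` column (and arbitrary metadata columns); every sample column in
#' the matrix must appear in the sheet. Empty cells and `NA` are read as
#' missing. Duplicate feature IDs are a hard error naming the duplicates.
#'
#' @param path matrix TSV path.
#' @param sample_sheet sample-sheet TSV path.
#' @param scale scale tag to attach (`"raw"` or `"log2_ratio"`).
#' @param stage_levels optional character vector giving the stage ordering; if
#'   omitted and the sheet has a `stage` column, levels are taken in order of
#'   first appearance.
#' @return [abundance_matrix()]
#' @export
read_abundance_matrix <- function(path, sample_sheet, scale = c("raw", "log2_ratio"),
                                  stage_levels = NULL) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (ncol(tab) < 2) stopf("matrix file %s has no sample columns", path)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stopf("duplicate feature IDs in %s: %s", path, paste(dup, collapse = ", "))
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  sheet <- utils::read.delim(sample_sheet, check.names = FALSE,
                             stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if ("stage" %in% names(sheet)) {
    lev <- stage_levels %||% unique(sheet$stage)
    sheet$stage <- factor(sheet$stage, levels = lev, ordered = TRUE)
  }
  abundance_matrix(vals, sheet, scale = scale)
}

#' Write an abundance matrix (and optionally its sample sheet) to TSV
#'
#' Inverse of [read_abundance_matrix()]: tab-separated, single header row,
#' first column `feature_id`, missing values written as `NA`.
#'
#' @param am [abundance_matrix()]
#' @param path output TSV path for the matrix.
#' @param sample_sheet_path optional output path for the sample sheet.
#' @export
write_abundance_matrix <- function(am, path, sample_sheet_path = NULL) {
  stopifnot(inherits(am, "abundance_matrix"))
  out <- data.frame(feature_id = rownames(am$values), am$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet_path)) {
    sheet <- am$samples
    if ("stage" %in% names(sheet)) sheet$stage <- as.character(sheet$stage)
    utils::write.table(sheet, sample_sheet_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a two-column ortholog mapping table
#'
#' TSV with header, first column human feature IDs, second column mouse
#' feature IDs. The mapping must be one-to-one (bijective over its domain);
#' any repeated ID on either side is a hard error.
#'
#' @param path TSV path.
#' @return data.frame with columns `human`, `mouse`.
#' @export
read_orthology_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2) stopf("orthology map %s needs two columns", path)
  map <- data.frame(human = as.character(tab[[1]]), mouse = as.character(tab[[2]]),
                    stringsAsFactors = FALSE)
  validate_orthology_map(map)
  map
}

validate_orthology_map <- function(map) {
  if (anyDuplicated(map$human) || anyDuplicated(map$mouse)) {
    stopf("orthology map is not one-to-one")
  }
  invisible(map)
}

#' Read a kinase-substrate table
#'
#' TSV with header and columns kinase, substrate (host protein ID), site
#' (residue letter + 1-based position, e.g. `S123`).
#'
#' @param path TSV path.
#' @return data.frame with columns `kinase`, `substrate`, `site`, and derived
#'   `site_id` (`"<substrate>_<site>"`).
#' @export
read_ks_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 3) stopf("kinase-substrate table %s needs three columns", path)
  ks <- data.frame(kinase = as.character(tab[[1]]),
                   substrate = as.character(tab[[2]]),
                   site = as.character(tab[[3]]),
                   stringsAsFactors = FALSE)
  bad <- !grepl("^[STY][0-9]+$", ks$site)
  if (any(bad)) stopf("malformed site strings: %s", paste(unique(ks$site[bad]), collapse = ", "))
  ks$site_id <- paste(ks$substrate, ks$site, sep = "_")
  ks
}
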