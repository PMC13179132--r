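#' Named gene-set collection with source tags
#'
#' Gene sets (protein complexes, pathways, GO terms, subcellular locations,
#' PPI partners, TF targets, kinase substrates, disease genes) keyed by name.
#' Each set carries a source tag used by downstream filtering and annotation
#' rules. Empty sets are dropped at construction with a warning.
#'
#' @param sets named list of character vectors (member IDs).
#' @param source character vector of source tags, recycled to `length(sets)`;
#'   one of `complex`, `pathway`, `go_bp`, `go_mf`, `go_cc`, `localization`,
#'   `ppi`, `tf_targets`, `kinase_substrates`, `disease`.
#' @return object of class `gene_set_collection`: list with `sets` (named list
#'   of unique member vectors) and `source` (named character).
#' @export
gene_set_collection <- function(sets, source = "complex") {
  if (is.null(names(sets)) || any(names(sets) == "")) stopf("all sets must be named")
  if (anyDuplicated(names(sets))) stopf("duplicate set names")
  source <- rep_len(source, length(sets))
  names(source) <- names(sets)
  sets <- lapply(sets, function(m) unique(as.character(m)))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warnf("dropping %d empty gene set(s): %s", sum(empty),
          paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
    source <- source[!empty]
  }
  structure(list(sets = sets, source = source), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %s)\n", length(x$sets),
              paste(range(lengths(x$sets)), collapse = "-")))
  cat("sources:", paste(names(table(x$source)), table(x$source), collapse = "; "), "\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. The source tag is taken from the description field when it is a
#' recognized tag, otherwise from `source`. Lines with no members are dropped
#' with a warning.
#'
#' @param path GMT path.
#' @param source fallback source tag for sets whose description is not a tag.
#' @return [gene_set_collection()]
#' @export
read_gmt <- function(path, source = "complex") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  known <- c("complex", "pathway", "go_bp", "go_mf", "go_cc", "localization",
             "ppi", "tf_targets", "kinase_substrates", "disease")
  sets <- list(); src <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    nm <- parts[1]
    desc <- if (length(parts) >= 2) parts[2] else ""
    members <- if (length(parts) > 2) parts[-(1:2)] else character()
    members <- members[nzchar(members)]
    sets[[nm]] <- members
    src <- c(src, if (desc %in% known) desc else source)
  }
  gene_set_collection(sets, src)
}

#' Write a gene-set collection to GMT
#'
#' The source tag goes in the description field, making [read_gmt()] the
#' exact inverse.
#'
#' @param gsc [gene_set_collection()]
#' @param path output path.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$source[[nm]], gsc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter gene sets by detected membership
#'
#' Keeps complexes/pathways (and all other non-GO sources) iff more than two
#' members are detected; GO sets (`go_bp`, `go_mf`, `go_cc`) additionally
#' require a total (pre-filter) size of at most `go_max_size` genes, guarding
#' against overly broad terms. Each kept set records its detected-member
#' subset in the `detected` element.
#'
#' @param gsc [gene_set_collection()]
#' @param detected character vector of detected feature IDs.
#' @param min_detected sets are kept iff strictly more than this many members
#'   are detected (default 2, i.e. 3+).
#' @param go_max_size maximum total size for GO sets (default 150).
#' @return `gene_set_collection` with an added `detected` list.
#' @export
filter_gene_sets <- function(gsc, detected, min_detected = 2, go_max_size = 150) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  detected <- unique(as.character(detected))
  det <- lapply(gsc$sets, function(m) intersect(m, detected))
  keep <- lengths(det) > min_detected
  is_go <- gsc$source %in% c("go_bp", "go_mf", "go_cc")
  keep <- keep & (!is_go | lengths(gsc$sets) <= go_max_size)
  out <- structure(list(sets = gsc$sets[keep], source = gsc$source[keep],
                        detected = det[keep]),
                   class = "gene_set_collection")
  out
}

# Detected members of a set, falling back to the full membership when the
# collection has not been filtered.
detected_members <- function(gsc, name) {
  if (!is.null(gsc$detected)) gsc$detected[[name]] else gsc$sets[[name]]
}
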