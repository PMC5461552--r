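#' Construct a pathway collection
#'
#' Named gene sets (KEGG-style). Used both to restrict the gene universe and
#' to pick, per target gene, the methylation features allowed in its design.
#'
#' @param sets named list of character vectors of gene IDs; empty sets are
#'   not allowed.
#' @param descriptions optional named character vector of free-text notes.
#' @return an object of class `pathway_collection`.
#' @export
pathway_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) stop("every pathway needs a name")
  .check_unique(names(sets), "pathway")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty)) {
    stop(sprintf("empty gene set(s): %s", paste(empty, collapse = ", ")))
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions[names(sets)]),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d pathways, %d distinct genes\n",
              length(x$sets), length(pathway_members(x))))
  invisible(x)
}

#' All genes that appear in at least one pathway
#' @param pc a [pathway_collection()].
#' @return character vector of gene IDs.
#' @export
pathway_members <- function(pc) unique(unlist(pc$sets, use.names = FALSE))

#' Pathways containing a given gene
#' @param pc a [pathway_collection()].
#' @param gene a gene ID.
#' @return character vector of pathway names (possibly empty).
#' @export
pathways_of <- function(pc, gene) {
  names(pc$sets)[vapply(pc$sets, function(s) gene %in% s, logical(1))]
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene IDs, tab-separated.
#' Duplicate genes within a line are stored once.
#'
#' @param path path to a .gmt file.
#' @return a [pathway_collection()].
#' @export
load_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1)
  descriptions <- stats::setNames(vapply(fields, `[`, character(1), 2), names(sets))
  pathway_collection(sets, descriptions)
}

#' Write gene sets in GMT format
#' @param pc a [pathway_collection()].
#' @param path output path.
#' @export
write_gmt <- function(pc, path) {
  lines <- vapply(names(pc$sets), function(nm) {
    paste(c(nm, pc$descriptions[[nm]], pc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a subtype assignment
#'
#' Maps every sample to its subtype. Each subtype must have at least two
#' samples: the between-subtype Kolmogorov-Smirnov distance is undefined for
#' singletons, so smaller groups are rejected up front.
#'
#' @param labels named character vector: names are sample IDs, values
#'   subtype names.
#' @param subtypes optional ordering of the subtype names; defaults to order
#'   of first appearance.
#' @return an object of class `subtype_assignment` with fields `labels`,
#'   `subtypes` and `counts`.
#' @export
subtype_assignment <- function(labels, subtypes = NULL) {
  if (is.null(names(labels)) || any(names(labels) == "")) {
    stop("labels must be named by sample ID")
  }
  .check_unique(names(labels), "sample")
  labels <- stats::setNames(as.character(labels), names(labels))
  if (anyNA(labels) || any(labels == "")) stop("sample with empty subtype label")
  if (is.null(subtypes)) subtypes <- unique(unname(labels))
  if (!setequal(subtypes, unique(labels))) {
    stop("subtypes must match the labels' subtype names")
  }
  counts <- stats::setNames(vapply(subtypes, function(s) sum(labels == s), integer(1)),
                            subtypes)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    stop(sprintf("subtype(s) with fewer than 2 samples: %s",
                 paste(small, collapse = ", ")))
  }
  structure(list(labels = labels, subtypes = subtypes, counts = counts),
            class = "subtype_assignment")
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat(sprintf("subtype_assignment: %d samples, %d subtypes (%s)\n",
              length(x$labels), length(x$subtypes),
              paste(sprintf("%s=%d", x$subtypes, x$counts), collapse = ", ")))
  invisible(x)
}

#' Read a sample-to-subtype table
#'
#' Two-column TSV (sample_id, subtype). A header row is auto-detected when
#' the first field equals `"sample"` (any case) or `"sample_id"`.
#'
#' @param path path to the TSV.
#' @return a [subtype_assignment()].
#' @export
load_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && tolower(fields[[1]][1]) %in% c("sample", "sample_id")) {
    fields <- fields[-1]
  }
  if (!length(fields)) stop("empty labels file")
  bad <- which(lengths(fields) < 2)
  if (length(bad)) stop(sprintf("labels line %d has fewer than 2 fields", bad[1]))
  labels <- stats::setNames(vapply(fields, `[`, character(1), 2),
                            vapply(fields, `[`, character(1), 1))
  subtype_assignment(labels)
}

#' Write a sample-to-subtype table
#' @param sa a [subtype_assignment()].
#' @param path output path.
#' @export
write_labels <- function(sa, path) {
  writeLines(c("sample_id\tsubtype",
               paste(names(sa$labels), sa$labels, sep = "\t")), path)
  invisible(path)
}

#' Construct a probe-to-gene map
#'
#' @param probe_id,gene_id character vectors of equal length; each probe maps
#'   to exactly one gene.
#' @return an object of class `probe_map` (a data frame).
#' @export
probe_map <- function(probe_id, gene_id) {
  probe_id <- as.character(probe_id)
  gene_id <- as.character(gene_id)
  if (length(probe_id) != length(gene_id)) stop("probe_id and gene_id lengths differ")
  .check_unique(probe_id, "probe")
  if (anyNA(gene_id) || any(gene_id == "")) stop("probe with empty gene ID")
  structure(data.frame(probe_id = probe_id, gene_id = gene_id,
                       stringsAsFactors = FALSE),
            class = c("probe_map", "data.frame"))
}

#' Read a two-column probe-to-gene TSV (probe_id, gene_id)
#' @param path path to the TSV; a `probe`/`probe_id` header is auto-detected.
#' @return a [probe_map()].
#' @export
load_probe_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && tolower(fields[[1]][1]) %in% c("probe", "probe_id")) {
    fields <- fields[-1]
  }
  if (!length(fields)) stop("empty probe map")
  probe_map(vapply(fields, `[`, character(1), 1),
            vapply(fields, `[`, character(1), 2))
}
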