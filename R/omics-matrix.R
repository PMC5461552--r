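#' Construct an omics matrix
#'
#' An `omics_matrix` is a numeric samples-by-features matrix with unique,
#' non-missing sample and feature identifiers. It is the shared container
#' for both expression (samples x genes) and methylation (samples x
#' genes-or-probes) data. Missing values are refused: upstream pipelines are
#' expected to have resolved them, and silent imputation would leak into the
#' regression fits.
#'
#' @param values numeric matrix, samples in rows.
#' @param sample_ids,feature_ids character vectors; default to the dimnames
#'   of `values`.
#' @return an object of class `omics_matrix` (a numeric matrix with dimnames).
#' @export
omics_matrix <- function(values, sample_ids = rownames(values),
                         feature_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric")
  if (is.null(sample_ids) || is.null(feature_ids)) {
    stop("sample and feature identifiers are required")
  }
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values)) stop("sample_ids length != nrow(values)")
  if (length(feature_ids) != ncol(values)) stop("feature_ids length != ncol(values)")
  .check_unique(sample_ids, "sample")
  .check_unique(feature_ids, "feature")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at sample '%s', feature '%s'",
                 sample_ids[idx[1]], feature_ids[idx[2]]))
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  class(values) <- c("omics_matrix", class(values))
  values
}

.check_unique <- function(ids, what) {
  if (anyNA(ids) || any(ids == "")) stop(sprintf("empty or missing %s identifier", what))
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop(sprintf("duplicate %s identifiers: %s", what,
                 paste(dups, collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d samples x %d features\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read a samples-by-features matrix from tab-separated text
#'
#' Expects a header row of feature identifiers and a leading column of sample
#' identifiers (or the transpose, per `orientation`). Duplicate identifiers,
#' non-numeric cells and missing values are errors, reported with their
#' coordinates.
#'
#' @param path path to a TSV file.
#' @param orientation `"samples_in_rows"` (default) or `"samples_in_columns"`.
#' @return an [omics_matrix()].
#' @export
load_matrix <- function(path, orientation = c("samples_in_rows", "samples_in_columns")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("matrix file needs a header row and at least one data row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  col_ids <- header[-1]
  row_ids <- vapply(cells[-1], `[`, character(1), 1)
  .check_unique(col_ids, if (orientation == "samples_in_rows") "feature" else "sample")
  .check_unique(row_ids, if (orientation == "samples_in_rows") "sample" else "feature")
  p <- length(col_ids)
  vals <- matrix(NA_real_, nrow = length(row_ids), ncol = p)
  for (i in seq_along(row_ids)) {
    row <- cells[[i + 1]][-1]
    if (length(row) != p) {
      stop(sprintf("row '%s' has %d values, expected %d", row_ids[i], length(row), p))
    }
    num <- suppressWarnings(as.numeric(row))
    bad <- which(is.na(num))
    if (length(bad)) {
      j <- bad[1]
      if (row[j] %in% c("", "NA", "na", "NaN")) {
        stop(sprintf("missing value at row '%s', column '%s'", row_ids[i], col_ids[j]))
      }
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   row[j], row_ids[i], col_ids[j]))
    }
    vals[i, ] <- num
  }
  dimnames(vals) <- list(row_ids, col_ids)
  if (orientation == "samples_in_columns") vals <- t(vals)
  omics_matrix(vals)
}

#' Write an omics matrix as tab-separated text
#'
#' Values are formatted at a fixed precision so that write/load round-trips
#' reproduce the file byte-for-byte.
#'
#' @param m an [omics_matrix()].
#' @param path output path.
#' @param digits significant digits used when formatting values.
#' @export
write_matrix <- function(m, path, digits = 12) {
  header <- paste(c("sample_id", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i],
            formatC(m[i, ], digits = digits, format = "g")), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Log-normalize a nonnegative matrix
#'
#' Applies the log(T + 1) transform entrywise (natural log). The base is a
#' monotone rescaling only; natural log is used throughout and recorded in
#' run provenance.
#'
#' @param m an [omics_matrix()] with all values >= 0.
#' @return the transformed [omics_matrix()].
#' @export
log_normalize <- function(m) {
  if (any(m < 0)) {
    idx <- which(unclass(m) < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at sample '%s', feature '%s'",
                 rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  out <- log1p(unclass(m))
  omics_matrix(out)
}

#' Keep only features that belong to at least one pathway
#'
#' Genes absent from every gene set are removed; this restricts both targets
#' and methylation features to genes with known pathway involvement. Column
#' order is preserved.
#'
#' @param m an [omics_matrix()].
#' @param pc a [pathway_collection()].
#' @return the filtered [omics_matrix()]; an empty result is an error.
#' @export
filter_by_pathway_membership <- function(m, pc) {
  members <- pathway_members(pc)
  keep <- colnames(m) %in% members
  if (!any(keep)) stop("no features remain after pathway-membership filtering")
  omics_matrix(unclass(m)[, keep, drop = FALSE])
}

#' Remove zero-heavy features
#'
#' Drops every column in which strictly more than `threshold` of the entries
#' are exactly zero ("more than half of patient records were zero"). Valid on
#' raw or log(T+1) data since zero maps to zero.
#'
#' @param m an [omics_matrix()].
#' @param threshold zero-fraction above which a column is dropped (default 0.5).
#' @return the filtered [omics_matrix()].
#' @export
filter_zero_heavy <- function(m, threshold = 0.5) {
  frac <- colMeans(unclass(m) == 0)
  keep <- frac <= threshold
  if (!any(keep)) stop("no features remain after zero-heavy filtering")
  omics_matrix(unclass(m)[, keep, drop = FALSE])
}

#' Collapse probe-level methylation to gene level
#'
#' When a gene is measured by several methylation probes, exactly one probe
#' is retained: the one whose Pearson correlation with the gene's expression
#' across shared samples is smallest. Under the default rule
#' (`"most_negative"`) this is the minimum signed correlation, favouring
#' promoter-like repressive probes; `"min_abs"` selects the probe with the
#' smallest absolute correlation instead. Probes whose correlation is
#' undefined (constant values) rank last; remaining ties break by probe ID.
#'
#' @param meth probe-level [omics_matrix()].
#' @param expr gene-level expression [omics_matrix()] over the same samples.
#' @param pm a [probe_map()].
#' @param rule probe-selection rule, `"most_negative"` (default) or `"min_abs"`.
#' @return a gene-level [omics_matrix()] whose columns are the chosen probes'
#'   values, one per gene present in both `pm` and `expr`.
#' @export
collapse_probes <- function(meth, expr, pm, rule = c("most_negative", "min_abs")) {
  rule <- match.arg(rule)
  if (!setequal(rownames(meth), rownames(expr))) {
    stop("methylation and expression matrices must cover the same samples")
  }
  meth <- unclass(meth)[rownames(expr), , drop = FALSE]
  missing_probes <- setdiff(pm$probe_id, colnames(meth))
  if (length(missing_probes)) {
    stop(sprintf("probes absent from methylation matrix: %s",
                 paste(missing_probes, collapse = ", ")))
  }
  genes <- unique(pm$gene_id)
  absent <- setdiff(genes, colnames(expr))
  if (length(absent)) {
    warning(sprintf("dropping probes for %d gene(s) without expression data: %s",
                    length(absent), paste(absent, collapse = ", ")))
    genes <- setdiff(genes, absent)
  }
  if (!length(genes)) stop("no genes with both probes and expression data")
  genes <- intersect(colnames(expr), genes)  # keep expression column order
  cols <- vapply(genes, function(g) {
    probes <- sort(pm$probe_id[pm$gene_id == g])
    r <- vapply(probes, function(p) {
      stats::cor(meth[, p], unclass(expr)[, g])
    }, numeric(1))
    if (rule == "min_abs") r <- abs(r)
    r[is.na(r)] <- Inf
    probes[which.min(r)]
  }, character(1))
  out <- meth[, cols, drop = FALSE]
  colnames(out) <- genes
  omics_matrix(out)
}
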