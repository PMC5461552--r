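#' Build the pathway-restricted design for one target gene
#'
#' The candidate methylation features for a target gene are the genes that
#' share at least one pathway with it (the union over all pathways the
#' target belongs to), intersected with the available methylation columns.
#' If the target gene itself is measured as a methylation feature it is kept
#' by default: a gene's own promoter methylation predicting its expression is
#' the canonical cis effect (`include_self = FALSE` drops it).
#'
#' Genes that belong to no pathway, or whose candidate feature set is empty,
#' are not estimable; `build_design()` returns `NULL` with a `reason`
#' attribute so callers can log the skip.
#'
#' @param target_gene a column of `expr`.
#' @param expr expression [omics_matrix()] (samples x genes).
#' @param meth methylation [omics_matrix()] over the same samples.
#' @param pc a [pathway_collection()].
#' @param include_self keep the target gene as its own feature when IDs
#'   collide? (default TRUE)
#' @return an object of class `gene_design` with fields `target_gene`,
#'   `feature_ids`, `X`, `y`, `sample_ids`; or a `design_skip` object
#'   carrying the reason when the gene is not estimable (see
#'   [is_design_skip()]).
#' @export
build_design <- function(target_gene, expr, meth, pc, include_self = TRUE) {
  if (!target_gene %in% colnames(expr)) {
    stop(sprintf("target gene '%s' is not an expression column", target_gene))
  }
  if (!setequal(rownames(expr), rownames(meth))) {
    stop("expression and methylation matrices must cover the same samples")
  }
  in_pathways <- pathways_of(pc, target_gene)
  if (!length(in_pathways)) {
    return(.skip_design(target_gene, "not a member of any pathway"))
  }
  co_members <- unique(unlist(pc$sets[in_pathways], use.names = FALSE))
  feature_ids <- sort(intersect(co_members, colnames(meth)))
  if (!include_self) feature_ids <- setdiff(feature_ids, target_gene)
  if (!length(feature_ids)) {
    return(.skip_design(target_gene, "no pathway co-member has methylation data"))
  }
  samples <- rownames(expr)
  structure(list(target_gene = target_gene,
                 feature_ids = feature_ids,
                 X = unclass(meth)[samples, feature_ids, drop = FALSE],
                 y = stats::setNames(unclass(expr)[samples, target_gene], samples),
                 sample_ids = samples),
            class = "gene_design")
}

.skip_design <- function(gene, reason) {
  structure(list(target_gene = gene, reason = reason), class = "design_skip")
}

#' Was a gene skipped during design construction?
#' @param x result of [build_design()].
#' @return TRUE when the gene was not estimable.
#' @export
is_design_skip <- function(x) inherits(x, "design_skip")

#' @export
print.gene_design <- function(x, ...) {
  cat(sprintf("gene_design: target %s, %d samples x %d features\n",
              x$target_gene, length(x$y), length(x$feature_ids)))
  invisible(x)
}

#' Build designs for many target genes
#'
#' @inheritParams build_design
#' @param genes target genes (default: all expression columns).
#' @return list with `designs` (named list of `gene_design`) and `skipped`
#'   (data frame of gene, reason).
#' @export
build_all_designs <- function(expr, meth, pc, genes = colnames(expr),
                              include_self = TRUE) {
  designs <- list()
  skipped <- list()
  for (g in genes) {
    d <- build_design(g, expr, meth, pc, include_self)
    if (is_design_skip(d)) {
      skipped[[g]] <- d$reason
    } else {
      designs[[g]] <- d
    }
  }
  skipped_df <- data.frame(gene = names(skipped),
                           reason = unlist(skipped, use.names = FALSE),
                           stringsAsFactors = FALSE)
  if (!nrow(skipped_df)) {
    skipped_df <- data.frame(gene = character(), reason = character(),
                             stringsAsFactors = FALSE)
  } else {
    for (i in seq_len(nrow(skipped_df))) {
      message(sprintf("skipping gene %s: %s", skipped_df$gene[i], skipped_df$reason[i]))
    }
  }
  list(designs = designs, skipped = skipped_df)
}
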