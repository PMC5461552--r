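#' Build per-subtype association networks from fitted coefficients
#'
#' One directed bipartite edge (methylation feature -> target gene) per
#' nonzero coefficient: an edge exists in subtype s's network when the
#' kernel-weighted fit for s gave that feature a coefficient with
#' `|beta| > tolerance`. The tolerance guards against solver coefficients
#' that are numerically, but not exactly, zero.
#'
#' @param fits a `kwl_fits` object from [fit_all()], or an equivalent
#'   long-form data frame with columns target_gene, subtype, feature, beta.
#' @param tolerance edges require `|beta|` strictly above this (default 1e-8).
#' @return an object of class `association_network`: list with `subtypes`
#'   and `edges` (data frame feature, gene, subtype, beta).
#' @export
build_networks <- function(fits, tolerance = 1e-8) {
  if (tolerance <= 0) stop("tolerance must be positive")
  if (inherits(fits, "kwl_fits")) {
    tab <- as.data.frame(fits, nonzero_only = FALSE)
    subtypes <- fits$subtypes
  } else {
    tab <- as.data.frame(fits)
    subtypes <- unique(tab$subtype)
  }
  keep <- abs(tab$beta) > tolerance
  edges <- data.frame(feature = tab$feature[keep], gene = tab$target_gene[keep],
                      subtype = tab$subtype[keep], beta = tab$beta[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$subtype, edges$feature, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(subtypes = subtypes, edges = edges, tolerance = tolerance),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  counts <- table(factor(x$edges$subtype, levels = x$subtypes))
  cat(sprintf("association_network: %d subtypes, edges per subtype: %s\n",
              length(x$subtypes),
              paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")))
  invisible(x)
}

#' Partition network edges by subtype membership
#'
#' Classifies every (feature, gene) pair in the union of the subtype
#' networks by the exact set of subtypes whose network contains it - the
#' cells of a Venn diagram over subtypes. Edge identity ignores the
#' coefficient value and sign. "Subtype-specific" edges are the cells of
#' size 1; the common core is the all-subtypes cell. Cell counts always sum
#' to the size of the edge union.
#'
#' @param net an [build_networks()] result.
#' @return an object of class `venn_partition`: list with `assignment`
#'   (data frame feature, gene, members, n_members), `cells` (data frame
#'   members, n_members, count), `n_union`, `subtypes`.
#' @export
venn_partition <- function(net) {
  if (!length(net$subtypes)) stop("network has no subtypes")
  e <- net$edges
  key <- paste(e$feature, e$gene, sep = "\r")
  members_by_key <- lapply(split(e$subtype, key), function(s) {
    net$subtypes[net$subtypes %in% s]  # canonical subtype order
  })
  keys <- names(members_by_key)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  assignment <- data.frame(
    feature = if (length(keys)) parts[, 1] else character(),
    gene = if (length(keys)) parts[, 2] else character(),
    members = vapply(members_by_key, paste, character(1), collapse = "|"),
    n_members = lengths(members_by_key),
    stringsAsFactors = FALSE)
  assignment <- assignment[order(assignment$members, assignment$feature,
                                 assignment$gene), , drop = FALSE]
  rownames(assignment) <- NULL
  if (nrow(assignment)) {
    cells <- stats::aggregate(list(count = rep(1L, nrow(assignment))),
                              by = list(members = assignment$members,
                                        n_members = assignment$n_members),
                              FUN = sum)
    cells <- cells[order(cells$n_members, cells$members), , drop = FALSE]
    rownames(cells) <- NULL
  } else {
    cells <- data.frame(members = character(), n_members = integer(),
                        count = integer(), stringsAsFactors = FALSE)
  }
  structure(list(assignment = assignment, cells = cells,
                 n_union = nrow(assignment), subtypes = net$subtypes),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  specific <- sum(x$cells$count[x$cells$n_members == 1])
  core <- x$cells$count[x$cells$n_members == length(x$subtypes)]
  cat(sprintf("venn_partition: %d edges in union; %d subtype-specific; %d in all subtypes\n",
              x$n_union, specific, if (length(core)) core else 0L))
  invisible(x)
}

#' Edges present in exactly one subtype's network
#'
#' @param net an [build_networks()] result.
#' @return data frame feature, gene, subtype (the single owning subtype).
#' @export
subtype_specific_edges <- function(net) {
  vp <- venn_partition(net)
  sp <- vp$assignment[vp$assignment$n_members == 1, , drop = FALSE]
  out <- data.frame(feature = sp$feature, gene = sp$gene, subtype = sp$members,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Hub degrees in the association network
#'
#' Degree of each node of the chosen role, by default over the
#' subtype-specific edges only (edges shared by two or more subtypes are
#' removed first, as in a subtype-specific network view); set
#' `specific_only = FALSE` to count over the full union. The table gives
#' the total degree and the per-subtype breakdown, whose row sum equals the
#' total; it is sorted by descending total degree with ties broken by node
#' ID.
#'
#' @param net an [build_networks()] result.
#' @param role `"methylation"` (feature side, default) or `"expression"`
#'   (gene side).
#' @param top_k optionally keep only the first `top_k` rows.
#' @param specific_only restrict to subtype-specific edges? (default TRUE)
#' @return data frame: node, total, then one degree column per subtype.
#' @export
hub_degrees <- function(net, role = c("methylation", "expression"),
                        top_k = NULL, specific_only = TRUE) {
  role <- match.arg(role)
  edges <- if (specific_only) {
    subtype_specific_edges(net)
  } else {
    unique(net$edges[, c("feature", "gene", "subtype")])
  }
  empty <- data.frame(node = character(), total = integer(),
                      stringsAsFactors = FALSE)
  for (s in net$subtypes) empty[[s]] <- integer()
  if (!nrow(edges)) return(empty)
  node <- if (role == "methylation") edges$feature else edges$gene
  tab <- table(node, factor(edges$subtype, levels = net$subtypes))
  out <- data.frame(node = rownames(tab), total = as.integer(rowSums(tab)),
                    stringsAsFactors = FALSE)
  for (s in net$subtypes) out[[s]] <- as.integer(tab[, s])
  out <- out[order(-out$total, out$node), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}

#' Export an association network
#'
#' Writes the network deterministically (edges sorted) in one of three
#' formats: a long-form edge-list TSV (feature, gene, subtype, beta,
#' venn_cell), SIF (`feature meth_assoc gene`, one file per subtype
#' combined with the subtype in the interaction column), or GraphML via
#' igraph with a `role` node attribute (`methylation`/`expression`) and
#' `subtype`, `beta`, `venn_cell` edge attributes.
#'
#' @param net an [build_networks()] result.
#' @param path output file path.
#' @param format `"tsv"`, `"sif"`, or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  vp <- venn_partition(net)
  cell <- stats::setNames(vp$assignment$members,
                          paste(vp$assignment$feature, vp$assignment$gene, sep = "\r"))
  e <- net$edges
  e$venn_cell <- unname(cell[paste(e$feature, e$gene, sep = "\r")])
  e <- e[order(e$subtype, e$feature, e$gene), , drop = FALSE]
  if (format == "tsv") {
    lines <- c("feature\tgene\tsubtype\tbeta\tvenn_cell",
               sprintf("%s\t%s\t%s\t%s\t%s", e$feature, e$gene, e$subtype,
                       formatC(e$beta, digits = 12, format = "g"), e$venn_cell))
    writeLines(lines, path)
  } else if (format == "sif") {
    writeLines(sprintf("%s\tmeth_assoc_%s\t%s", e$feature, e$subtype, e$gene), path)
  } else {
    g <- .network_igraph(net, e)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

.network_igraph <- function(net, e) {
  features <- sort(unique(e$feature))
  genes <- sort(unique(e$gene))
  nodes <- data.frame(
    name = c(paste0("M:", features), paste0("E:", genes)),
    label = c(features, genes),
    role = c(rep("methylation", length(features)), rep("expression", length(genes))),
    stringsAsFactors = FALSE)
  edges_df <- data.frame(from = paste0("M:", e$feature), to = paste0("E:", e$gene),
                         subtype = e$subtype, beta = e$beta,
                         venn_cell = e$venn_cell, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges_df, directed = TRUE, vertices = nodes)
}

#' Read an association network from an edge-list TSV
#'
#' Inverse of [export_network()] with `format = "tsv"`.
#'
#' @param path path to the TSV.
#' @param tolerance stored on the resulting object (default 1e-8).
#' @param subtypes optional canonical subtype ordering; defaults to order of
#'   appearance.
#' @return an `association_network`.
#' @export
load_network <- function(path, tolerance = 1e-8, subtypes = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("feature", "gene", "subtype", "beta")
  if (!all(need %in% names(tab))) {
    stop("edge-list TSV must have columns feature, gene, subtype, beta")
  }
  if (is.null(subtypes)) subtypes <- unique(tab$subtype)
  edges <- tab[order(tab$subtype, tab$feature, tab$gene),
               need, drop = FALSE]
  rownames(edges) <- NULL
  structure(list(subtypes = subtypes, edges = edges, tolerance = tolerance),
            class = "association_network")
}
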