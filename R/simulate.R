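#' Configuration for the synthetic multi-subtype generator
#'
#' Defaults emulate the structure of a multi-subtype tumour cohort at desk
#' scale: four subtypes of very unequal size (the 16/306/42/73 shape scaled
#' down by ~5), log-scale positive methylation values, per-gene sparse
#' linear methylation-to-expression effects with a large component shared
#' by all subtypes plus a small subtype-specific component, and
#' pathway-structured feature groups. A per-subtype location shift of the
#' methylation distribution drives the between-subtype KS distances.
#'
#' @param n_per_subtype named integer vector of samples per subtype.
#' @param p_features number of methylation features.
#' @param n_genes number of expression target genes.
#' @param n_pathways number of gene sets; features are split into
#'   contiguous blocks, one per pathway, and targets are assigned
#'   round-robin.
#' @param shared_support_size nonzero coefficients common to all subtypes,
#'   per gene.
#' @param specific_support_size extra nonzero coefficients private to each
#'   subtype, per gene (disjoint across subtypes when the pathway block is
#'   large enough).
#' @param effect_size absolute value of the shared true coefficients.
#' @param specific_effect_size absolute value of the subtype-specific true
#'   coefficients; defaults to half of `effect_size`, so the shared
#'   component dominates and subtypes remain variations on one regulatory
#'   program rather than unrelated models.
#' @param noise_sigma standard deviation of the Gaussian noise on log-scale
#'   expression.
#' @param subtype_shift named numeric vector: per-subtype location shift of
#'   log-scale methylation (0 = identical distributions).
#' @param shift_fraction fraction of features that carry the subtype shift
#'   (default 0.5). Shifting only a subset mimics subtype-differential
#'   methylation of a limited set of loci and keeps the features from
#'   sharing one global subtype factor.
#' @param meanlog,sdlog parameters of the lognormal base distribution of
#'   log-scale methylation values.
#' @param seed integer seed; generation is a pure function of the config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_per_subtype = c(HER2 = 4, LuminalA = 60,
                                         LuminalB = 10, TripleNegative = 16),
                       p_features = 50, n_genes = 10, n_pathways = 4,
                       shared_support_size = 3, specific_support_size = 2,
                       effect_size = 1, specific_effect_size = effect_size / 2,
                       noise_sigma = 0.5,
                       subtype_shift = NULL, shift_fraction = 0.5,
                       meanlog = 0, sdlog = 0.5, seed = 1) {
  n_per_subtype <- unlist(n_per_subtype)  # accept YAML/JSON maps
  if (!is.null(subtype_shift)) subtype_shift <- unlist(subtype_shift)
  if (is.null(names(n_per_subtype)) || any(names(n_per_subtype) == "")) {
    stop("n_per_subtype must be named by subtype")
  }
  if (any(n_per_subtype < 2)) stop("every subtype needs at least 2 samples")
  if (is.null(subtype_shift)) {
    subtype_shift <- stats::setNames(
      0.8 * (seq_along(n_per_subtype) - 1), names(n_per_subtype))
  }
  if (!setequal(names(subtype_shift), names(n_per_subtype))) {
    stop("subtype_shift must be named like n_per_subtype")
  }
  if (noise_sigma <= 0) stop("noise_sigma must be positive")
  if (shift_fraction < 0 || shift_fraction > 1) {
    stop("shift_fraction must be in [0, 1]")
  }
  if (p_features < n_pathways) stop("need at least one feature per pathway")
  if (specific_support_size > p_features) {
    stop("specific_support_size cannot exceed p_features")
  }
  block <- p_features %/% n_pathways
  if (shared_support_size + specific_support_size > block) {
    stop("pathway blocks too small for the requested supports")
  }
  structure(list(n_per_subtype = n_per_subtype, p_features = p_features,
                 n_genes = n_genes, n_pathways = n_pathways,
                 shared_support_size = shared_support_size,
                 specific_support_size = specific_support_size,
                 effect_size = effect_size,
                 specific_effect_size = specific_effect_size,
                 noise_sigma = noise_sigma,
                 subtype_shift = subtype_shift[names(n_per_subtype)],
                 shift_fraction = shift_fraction,
                 meanlog = meanlog, sdlog = sdlog, seed = seed),
            class = "sim_config")
}

.pad_ids <- function(prefix, n) sprintf("%s%0*d", prefix, max(2, nchar(n)), seq_len(n))

#' Generate a synthetic multi-subtype methylation/expression bundle
#'
#' Log-scale methylation is drawn i.i.d. lognormal per entry plus the
#' subtype's location shift; log-scale expression of each target gene is a
#' sparse linear function of the methylation features in the gene's pathway
#' block (shared support plus the sample's subtype-specific support) plus
#' Gaussian noise, offset per gene so it stays nonnegative. Stored
#' matrices are `exp(value) - 1`, i.e. nonnegative raw inputs that
#' [log_normalize()] maps back to the log scale exactly.
#'
#' @param cfg a [sim_config()].
#' @return list with `meth` and `expr` ([omics_matrix()] of raw values),
#'   `sa` ([subtype_assignment()]), `pc` ([pathway_collection()]), `truth`
#'   (list: `coefficients` long data frame with gene, subtype, feature,
#'   beta, type; `intercepts`; `edges` with shared/specific labels), and
#'   `config`.
#' @export
generate <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  subtypes <- names(cfg$n_per_subtype)
  n <- sum(cfg$n_per_subtype)
  sample_ids <- .pad_ids("S", n)
  labels <- stats::setNames(rep(subtypes, cfg$n_per_subtype), sample_ids)
  features <- .pad_ids("MF", cfg$p_features)
  genes <- .pad_ids("TG", cfg$n_genes)

  # contiguous feature blocks, one per pathway; targets dealt round-robin
  block_of <- sort(rep_len(seq_len(cfg$n_pathways), cfg$p_features))
  sets <- lapply(seq_len(cfg$n_pathways), function(k) features[block_of == k])
  gene_pathway <- rep_len(seq_len(cfg$n_pathways), cfg$n_genes)
  for (k in seq_len(cfg$n_pathways)) {
    sets[[k]] <- c(sets[[k]], genes[gene_pathway == k])
  }
  names(sets) <- .pad_ids("PW", cfg$n_pathways)
  pc <- pathway_collection(sets, stats::setNames(
    sprintf("synthetic pathway block %d", seq_len(cfg$n_pathways)), names(sets)))

  withr::with_seed(cfg$seed, {
    X <- matrix(stats::rlnorm(n * cfg$p_features, cfg$meanlog, cfg$sdlog),
                n, cfg$p_features, dimnames = list(sample_ids, features))
    n_shifted <- round(cfg$shift_fraction * cfg$p_features)
    shifted <- sample(cfg$p_features, n_shifted)
    X[, shifted] <- X[, shifted] + cfg$subtype_shift[labels]
    coef_rows <- list()
    intercepts <- stats::setNames(numeric(cfg$n_genes), genes)
    Y <- matrix(0, n, cfg$n_genes, dimnames = list(sample_ids, genes))
    for (gi in seq_len(cfg$n_genes)) {
      g <- genes[gi]
      block <- features[block_of == gene_pathway[gi]]
      shared <- sample(block, cfg$shared_support_size)
      pool <- setdiff(block, shared)
      specific <- list()
      for (s in subtypes) {
        if (cfg$specific_support_size == 0) { specific[[s]] <- character(); next }
        if (length(pool) < cfg$specific_support_size) {
          pool <- setdiff(block, shared)  # pool exhausted: allow overlap across subtypes
        }
        specific[[s]] <- sample(pool, cfg$specific_support_size)
        pool <- setdiff(pool, specific[[s]])
      }
      shared_sign <- sample(c(-1, 1), length(shared), replace = TRUE)
      beta_s <- list()
      for (s in subtypes) {
        b <- stats::setNames(numeric(length(block)), block)
        b[shared] <- shared_sign * cfg$effect_size
        b[specific[[s]]] <- sample(c(-1, 1), length(specific[[s]]),
                                   replace = TRUE) * cfg$specific_effect_size
        beta_s[[s]] <- b
        nz <- b != 0
        coef_rows[[paste(g, s)]] <- data.frame(
          gene = g, subtype = s, feature = block[nz], beta = unname(b[nz]),
          type = ifelse(block[nz] %in% shared, "shared", "specific"),
          stringsAsFactors = FALSE)
      }
      lin <- numeric(n)
      for (s in subtypes) {
        rows <- labels == s
        lin[rows] <- X[rows, block, drop = FALSE] %*% beta_s[[s]]
      }
      ylog <- lin + stats::rnorm(n, 0, cfg$noise_sigma)
      intercepts[g] <- max(0, -min(ylog))  # keep stored expression nonnegative
      Y[, gi] <- ylog + intercepts[g]
    }
  })
  truth_coef <- do.call(rbind, coef_rows)
  rownames(truth_coef) <- NULL
  edges <- truth_coef[, c("feature", "gene", "subtype", "type")]
  list(meth = omics_matrix(expm1(X)), expr = omics_matrix(expm1(Y)),
       sa = subtype_assignment(labels, subtypes), pc = pc,
       truth = list(coefficients = truth_coef, intercepts = intercepts,
                    edges = edges),
       config = cfg)
}

#' Planted subtype-specific edges of a generated bundle
#'
#' Edges whose true coefficient is nonzero in exactly one subtype - the
#' ground truth against which recovered Venn "specific" cells are scored.
#'
#' @param bundle a [generate()] result.
#' @return data frame feature, gene, subtype.
#' @export
true_specific_edges <- function(bundle) {
  e <- bundle$truth$edges
  key <- paste(e$feature, e$gene, sep = "\r")
  cnt <- table(key)
  specific <- e[key %in% names(cnt)[cnt == 1] & e$type == "specific", , drop = FALSE]
  out <- specific[order(specific$subtype, specific$feature, specific$gene),
                  c("feature", "gene", "subtype")]
  rownames(out) <- NULL
  out
}

#' Write a generated bundle as plain-text fixture files
#'
#' Writes `expr.tsv`, `meth.tsv` (raw values, samples in rows),
#' `labels.tsv`, `pathways.gmt`, `truth.tsv` and a `manifest.json`
#' recording the config and seed - all in the formats the loaders read, so
#' generate/write/load round-trips are exact at the written precision and
#' two runs with the same seed produce byte-identical files.
#'
#' @param bundle a [generate()] result.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create directory %s", out_dir))
  paths <- c(expr = file.path(out_dir, "expr.tsv"),
             meth = file.path(out_dir, "meth.tsv"),
             labels = file.path(out_dir, "labels.tsv"),
             gmt = file.path(out_dir, "pathways.gmt"),
             truth = file.path(out_dir, "truth.tsv"),
             manifest = file.path(out_dir, "manifest.json"))
  write_matrix(bundle$expr, paths["expr"])
  write_matrix(bundle$meth, paths["meth"])
  write_labels(bundle$sa, paths["labels"])
  write_gmt(bundle$pc, paths["gmt"])
  tc <- bundle$truth$coefficients
  writeLines(c("gene\tsubtype\tfeature\tbeta\ttype",
               sprintf("%s\t%s\t%s\t%s\t%s", tc$gene, tc$subtype, tc$feature,
                       formatC(tc$beta, digits = 12, format = "g"), tc$type)),
             paths["truth"])
  cfg <- unclass(bundle$config)
  jsonlite::write_json(cfg, paths["manifest"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
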