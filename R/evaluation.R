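#' Cross-validated per-subtype prediction error for one gene
#'
#' Outer k-fold cross-validation (stratified by subtype) comparing three
#' estimators of the same gene:
#'
#' * `kernel_weighted` - all training samples, RBF-kernel weights toward
#'   the target subtype;
#' * `separate` - plain lasso on the target subtype's training samples only;
#' * `pooled` - plain lasso on all training samples, ignoring subtypes.
#'
#' Within each outer fold the penalty is chosen by inner cross-validation on
#' the training samples; for `kernel_weighted` the bandwidth can be tuned
#' the same way via `h_grid`, nested inside the outer loop so the test fold
#' never influences it. Squared errors are pooled over folds per subtype
#' and one root is taken at the end (stable for tiny subtypes, where
#' per-fold RMSEs would average one or two samples).
#'
#' @param design a [build_design()] result.
#' @param sa a [subtype_assignment()].
#' @param sk a [subtype_kernel()]; its bandwidth is used for
#'   `kernel_weighted` unless `h_grid` is given, and its distance matrix is
#'   used either way.
#' @param methods subset of `c("kernel_weighted", "separate", "pooled")`.
#' @param nfolds outer (and inner) fold count.
#' @param seed integer seed; outer and inner folds derive from it.
#' @param h_grid optional bandwidth grid for nested tuning.
#' @param intercept,standardize passed to the solver.
#' @return data frame with columns target_gene, subtype, method, rmse,
#'   n_test.
#' @export
cv_rmse <- function(design, sa, sk,
                    methods = c("kernel_weighted", "separate", "pooled"),
                    nfolds = 5, seed = 1, h_grid = NULL,
                    intercept = TRUE, standardize = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  labels <- unname(sa$labels[design$sample_ids])
  folds <- make_folds(labels, nfolds, seed)
  X <- design$X
  y <- design$y
  acc <- list()  # per (subtype, method): sse, n
  add_err <- function(subtype, method, resid) {
    key <- paste(subtype, method, sep = "|")
    prev <- acc[[key]]
    if (is.null(prev)) prev <- c(sse = 0, n = 0)
    acc[[key]] <<- c(sse = prev[["sse"]] + sum(resid^2),
                     n = prev[["n"]] + length(resid))
  }
  for (f in sort(unique(folds))) {
    test <- folds == f
    Xtr <- X[!test, , drop = FALSE]
    ytr <- y[!test]
    ltr <- labels[!test]
    Xte <- X[test, , drop = FALSE]
    yte <- y[test]
    lte <- labels[test]
    inner_seed <- seed + 1000L * f
    if ("pooled" %in% methods) {
      sel <- select_lambda(Xtr, ytr, labels = ltr, nfolds = nfolds,
                           seed = inner_seed, intercept = intercept,
                           standardize = standardize)
      fit <- fit_weighted_lasso(Xtr, ytr, lambda = sel$lambda,
                                intercept = intercept, standardize = standardize)
      pred <- predict_lasso(fit$beta, fit$intercept, Xte)
      for (s in unique(lte)) add_err(s, "pooled", (yte - pred)[lte == s])
    }
    if ("separate" %in% methods) {
      for (s in unique(lte)) {
        tr_s <- ltr == s
        if (sum(tr_s) < 2) next  # too few training samples to fit at all
        k <- min(nfolds, sum(tr_s))
        sel <- if (k >= 2) {
          select_lambda(Xtr[tr_s, , drop = FALSE], ytr[tr_s],
                        nfolds = k, seed = inner_seed,
                        intercept = intercept, standardize = standardize)
        } else NULL
        lam <- if (is.null(sel)) lambda_grid(Xtr[tr_s, , drop = FALSE], ytr[tr_s])[25] else sel$lambda
        fit <- fit_weighted_lasso(Xtr[tr_s, , drop = FALSE], ytr[tr_s],
                                  lambda = lam, intercept = intercept,
                                  standardize = standardize)
        pred <- predict_lasso(fit$beta, fit$intercept, Xte[lte == s, , drop = FALSE])
        add_err(s, "separate", yte[lte == s] - pred)
      }
    }
    if ("kernel_weighted" %in% methods) {
      for (s in unique(lte)) {
        if (!is.null(h_grid)) {
          # nested bandwidth tuning on the training fold, scored by held-out
          # target-subtype error (see select_bandwidth)
          tune <- vapply(h_grid, function(h) {
            w <- sample_weights_for_target(subtype_kernel(sk$dist, h), sa, s,
                                           design$sample_ids)[!test]
            .target_cv_score(Xtr, ytr, w, ltr, s, nfolds = nfolds,
                             seed = inner_seed, intercept = intercept,
                             standardize = standardize)
          }, numeric(1))
          h_use <- h_grid[which.min(tune)]
        } else {
          h_use <- sk$h
        }
        sk_use <- subtype_kernel(sk$dist, h_use)
        w <- sample_weights_for_target(sk_use, sa, s, design$sample_ids)[!test]
        sel <- select_lambda(Xtr, ytr, w, ltr, nfolds = nfolds,
                             seed = inner_seed, intercept = intercept,
                             standardize = standardize)
        fit <- fit_weighted_lasso(Xtr, ytr, w, sel$lambda,
                                  intercept = intercept, standardize = standardize)
        pred <- predict_lasso(fit$beta, fit$intercept, Xte[lte == s, , drop = FALSE])
        add_err(s, "kernel_weighted", yte[lte == s] - pred)
      }
    }
  }
  keys <- strsplit(names(acc), "|", fixed = TRUE)
  out <- data.frame(target_gene = design$target_gene,
                    subtype = vapply(keys, `[`, character(1), 1),
                    method = vapply(keys, `[`, character(1), 2),
                    rmse = vapply(acc, function(a) sqrt(a[["sse"]] / a[["n"]]), numeric(1)),
                    n_test = vapply(acc, function(a) as.integer(a[["n"]]), integer(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$subtype, out$method), , drop = FALSE]
}

#' Cross-validated comparison over many genes
#'
#' Runs [cv_rmse()] for each estimable target gene and stacks the records.
#'
#' @inheritParams fit_all
#' @inheritParams cv_rmse
#' @return data frame of [cv_rmse()] records for all genes.
#' @export
evaluate_genes <- function(expr, meth, pc, sa, sk, genes = colnames(expr),
                           methods = c("kernel_weighted", "separate", "pooled"),
                           nfolds = 5, seed = 1, h_grid = NULL,
                           include_self = TRUE, intercept = TRUE,
                           standardize = TRUE) {
  built <- build_all_designs(expr, meth, pc, genes, include_self)
  recs <- lapply(built$designs, cv_rmse, sa = sa, sk = sk, methods = methods,
                 nfolds = nfolds, seed = seed, h_grid = h_grid,
                 intercept = intercept, standardize = standardize)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Rank target genes by prediction quality
#'
#' Two views of an evaluation table:
#' * `overall` - genes ordered by mean kernel-weighted RMSE across
#'   subtypes, ascending (best-estimated first);
#' * `by_subtype` - per subtype, genes ordered by the improvement of the
#'   kernel-weighted estimate over the pooled plain lasso
#'   (pooled RMSE - kernel RMSE), descending, i.e. the genes that gain most
#'   from subtype information.
#'
#' Ties break by gene ID so rankings are reproducible.
#'
#' @param records a data frame from [evaluate_genes()]/[cv_rmse()].
#' @param top_k optionally truncate each list to its first `top_k` genes.
#' @return list with `overall` (data frame gene, rmse) and `by_subtype`
#'   (named list of data frames gene, improvement).
#' @export
rank_genes <- function(records, top_k = NULL) {
  kw <- records[records$method == "kernel_weighted", , drop = FALSE]
  overall <- stats::aggregate(rmse ~ target_gene, data = kw, FUN = mean)
  overall <- overall[order(overall$rmse, overall$target_gene), , drop = FALSE]
  names(overall) <- c("gene", "rmse")
  rownames(overall) <- NULL
  by_subtype <- list()
  pooled <- records[records$method == "pooled", , drop = FALSE]
  if (nrow(pooled) && nrow(kw)) {
    for (s in unique(kw$subtype)) {
      a <- kw[kw$subtype == s, c("target_gene", "rmse")]
      b <- pooled[pooled$subtype == s, c("target_gene", "rmse")]
      m <- merge(a, b, by = "target_gene", suffixes = c("_kw", "_pooled"))
      m$improvement <- m$rmse_pooled - m$rmse_kw
      m <- m[order(-m$improvement, m$target_gene), c("target_gene", "improvement")]
      names(m) <- c("gene", "improvement")
      rownames(m) <- NULL
      by_subtype[[s]] <- m
    }
  }
  if (!is.null(top_k)) {
    overall <- utils::head(overall, top_k)
    by_subtype <- lapply(by_subtype, utils::head, top_k)
  }
  list(overall = overall, by_subtype = by_subtype)
}

#' Pathway-level prediction scores
#'
#' Scores each pathway by summing a per-gene error statistic over its member
#' genes present in the records: `statistic = "rmse"` sums mean
#' kernel-weighted RMSEs (low = well-estimated pathway, the overall
#' ranking); `statistic = "improvement"` sums pooled-minus-kernel RMSE
#' improvements per subtype (high = pathway that benefits from subtype
#' information). Genes in several pathways count once per containing
#' pathway. Pathways with no scored member genes are dropped with a
#' warning.
#'
#' @param records a data frame from [evaluate_genes()].
#' @param pc a [pathway_collection()].
#' @param statistic `"rmse"` or `"improvement"`.
#' @param subtype required when `statistic = "improvement"`: which subtype's
#'   improvements to sum.
#' @return data frame with columns pathway, score, n_genes, ordered
#'   best-first (ascending rmse / descending improvement; ties by pathway
#'   name).
#' @export
pathway_error <- function(records, pc, statistic = c("rmse", "improvement"),
                          subtype = NULL) {
  statistic <- match.arg(statistic)
  if (statistic == "rmse") {
    kw <- records[records$method == "kernel_weighted", , drop = FALSE]
    per_gene <- stats::aggregate(rmse ~ target_gene, data = kw, FUN = mean)
    value <- stats::setNames(per_gene$rmse, per_gene$target_gene)
  } else {
    if (is.null(subtype)) stop("statistic = 'improvement' needs a subtype")
    rk <- rank_genes(records)
    imp <- rk$by_subtype[[subtype]]
    if (is.null(imp)) stop(sprintf("no records for subtype '%s'", subtype))
    value <- stats::setNames(imp$improvement, imp$gene)
  }
  rows <- lapply(names(pc$sets), function(p) {
    members <- intersect(pc$sets[[p]], names(value))
    if (!length(members)) return(NULL)
    data.frame(pathway = p, score = sum(value[members]),
               n_genes = length(members), stringsAsFactors = FALSE)
  })
  dropped <- names(pc$sets)[vapply(rows, is.null, logical(1))]
  if (length(dropped)) {
    warning(sprintf("pathway(s) with no scored genes omitted: %s",
                    paste(dropped, collapse = ", ")))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no pathway has scored member genes")
  out <- if (statistic == "rmse") {
    out[order(out$score, out$pathway), , drop = FALSE]
  } else {
    out[order(-out$score, out$pathway), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
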