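#' Stratified cross-validation folds
#'
#' Assigns each sample to one of `nfolds` folds, stratified by subtype:
#' within each subtype, samples are shuffled (deterministically given
#' `seed`) and dealt round-robin, so every fold's subtype composition
#' mirrors the full data as closely as the counts allow. Subtypes with fewer
#' samples than folds end up absent from some folds; each of their samples
#' is still held out exactly once (effectively leave-one-out for that
#' subtype).
#'
#' @param labels character vector of subtype labels, one per sample.
#' @param nfolds number of folds (>= 2).
#' @param seed integer seed; fold assignment is a pure function of
#'   `(labels, nfolds, seed)`.
#' @return integer vector of fold memberships in `1:nfolds`.
#' @export
make_folds <- function(labels, nfolds = 5, seed = 1) {
  if (nfolds < 2) stop("nfolds must be at least 2")
  n <- length(labels)
  if (n < nfolds) stop("fewer samples than folds")
  folds <- integer(n)
  withr::with_seed(seed, {
    for (s in unique(labels)) {
      idx <- which(labels == s)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(nfolds), length(idx))
    }
  })
  folds
}

#' Select the lasso penalty by weighted cross-validation
#'
#' Grid search over a decreasing penalty sequence: each fold's model is fit
#' on the remaining folds (with the observation weights), held-out samples
#' are predicted, and the criterion is the weighted mean squared error
#' pooled over folds, using the same observation weights - so samples near
#' the target subtype dominate the choice of lambda just as they dominate
#' the fit. Ties are broken toward the smallest lambda (the denser model).
#'
#' `rule = "min"` (default) returns the error-minimising lambda, the usual
#' choice when prediction accuracy is the goal. `rule = "1se"` returns the
#' largest lambda whose error is within one standard error (over folds) of
#' the minimum; the minimiser is known to over-select noise features, so
#' the sparser one-standard-error model is the better default when the
#' selected support itself is the quantity of interest (e.g. association
#' networks).
#'
#' @inheritParams fit_weighted_lasso
#' @param labels subtype labels used to stratify folds.
#' @param lambda decreasing penalty grid; default [lambda_grid()] on the
#'   full data.
#' @param nfolds number of folds.
#' @param seed integer seed controlling fold assignment.
#' @param rule `"min"` or `"1se"` (see Details).
#' @return list with `lambda` (the selected value under `rule`),
#'   `lambda_min`, `lambda_1se`, `cvm` (weighted MSE per grid point), `cvse`
#'   (its standard error over folds), `cv_rmse` (root of the minimum),
#'   `lambda_seq`, `folds`.
#' @export
select_lambda <- function(X, y, weights = rep(1, nrow(as.matrix(X))),
                          labels = rep("all", nrow(as.matrix(X))),
                          lambda = NULL, nfolds = 5, seed = 1,
                          intercept = TRUE, standardize = TRUE,
                          rule = c("min", "1se")) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  if (is.null(lambda)) {
    lambda <- lambda_grid(X, y, weights, intercept = intercept,
                          standardize = standardize)
  }
  if (length(lambda) > 1 && is.unsorted(rev(lambda))) {
    stop("lambda grid must be non-increasing")
  }
  folds <- make_folds(labels, nfolds, seed)
  fold_ids <- sort(unique(folds))
  sse <- numeric(length(lambda))
  swt <- 0
  fold_mse <- matrix(NA_real_, length(fold_ids), length(lambda))
  for (k in seq_along(fold_ids)) {
    test <- folds == fold_ids[k]
    w_test <- weights[test]
    if (sum(weights[!test]) <= 0) {
      stop(sprintf("fold %d has zero training weight", fold_ids[k]))
    }
    fit <- fit_weighted_lasso_path(X[!test, , drop = FALSE], y[!test],
                                   weights[!test], lambda,
                                   intercept = intercept, standardize = standardize)
    pred <- predict_lasso(fit$beta, fit$intercept, X[test, , drop = FALSE])
    err <- (y[test] - pred)^2  # n_test x L
    sse <- sse + colSums(err * w_test)
    swt <- swt + sum(w_test)
    if (sum(w_test) > 0) fold_mse[k, ] <- colSums(err * w_test) / sum(w_test)
  }
  if (swt <= 0) stop("zero total test weight across folds")
  cvm <- sse / swt
  cvse <- apply(fold_mse, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) return(0)
    stats::sd(v) / sqrt(length(v))
  })
  best <- which(cvm <= min(cvm) + 1e-15)
  i_min <- max(best)  # smallest lambda among ties
  lambda_min <- lambda[i_min]
  lambda_1se <- max(lambda[cvm <= cvm[i_min] + cvse[i_min]])
  list(lambda = if (rule == "min") lambda_min else lambda_1se,
       lambda_min = lambda_min, lambda_1se = lambda_1se,
       cvm = cvm, cvse = cvse, cv_rmse = sqrt(min(cvm)),
       lambda_seq = lambda, folds = folds)
}

#' Fit one target gene for one target subtype
#'
#' The kernel-weighted estimate: all samples enter the fit, each weighted by
#' the RBF kernel of the KS distance between its subtype and the target
#' subtype. The penalty is chosen by weighted cross-validation on the
#' gene's own grid, then the final model is refit on all samples at that
#' penalty.
#'
#' @param design a [build_design()] result.
#' @param sk a [subtype_kernel()].
#' @param sa a [subtype_assignment()].
#' @param target_subtype which subtype's coefficients to estimate.
#' @param nfolds folds for penalty selection.
#' @param seed integer seed.
#' @param lambda optional fixed penalty (skips cross-validation).
#' @param intercept,standardize passed to the solver.
#' @param rule penalty-selection rule, `"min"` or `"1se"` (see
#'   [select_lambda()]).
#' @return an object of class `gene_fit`: `target_gene`, `subtype`, `beta`
#'   (named, original scale), `intercept`, `lambda`, `h`, `cv_rmse`.
#' @export
fit_gene_for_subtype <- function(design, sk, sa, target_subtype,
                                 nfolds = 5, seed = 1, lambda = NULL,
                                 intercept = TRUE, standardize = TRUE,
                                 rule = c("min", "1se")) {
  w <- sample_weights_for_target(sk, sa, target_subtype, design$sample_ids)
  labels <- unname(sa$labels[design$sample_ids])
  cv_rmse <- NA_real_
  if (is.null(lambda)) {
    sel <- select_lambda(design$X, design$y, w, labels, nfolds = nfolds,
                         seed = seed, intercept = intercept,
                         standardize = standardize, rule = rule)
    lambda <- sel$lambda
    cv_rmse <- sel$cv_rmse
  }
  fit <- fit_weighted_lasso(design$X, design$y, w, lambda,
                            intercept = intercept, standardize = standardize)
  structure(list(target_gene = design$target_gene, subtype = target_subtype,
                 beta = fit$beta, intercept = fit$intercept,
                 lambda = lambda, h = sk$h, cv_rmse = cv_rmse),
            class = "gene_fit")
}

#' @export
print.gene_fit <- function(x, ...) {
  cat(sprintf("gene_fit: %s | %s | %d/%d nonzero | lambda = %.4g | cv_rmse = %.4g\n",
              x$target_gene, x$subtype, sum(x$beta != 0), length(x$beta),
              x$lambda, x$cv_rmse))
  invisible(x)
}

#' Fit all target genes for all subtypes
#'
#' One [fit_gene_for_subtype()] per (estimable gene, subtype). Fits are
#' independent and seeded per call, so results do not depend on execution
#' order; genes that cannot be estimated are recorded with their reasons.
#'
#' @inheritParams build_all_designs
#' @param sk a [subtype_kernel()].
#' @param sa a [subtype_assignment()].
#' @param genes target genes (default: all expression columns).
#' @param nfolds,seed,lambda,intercept,standardize,rule passed to
#'   [fit_gene_for_subtype()].
#' @return an object of class `kwl_fits`: list with `fits` (list of
#'   `gene_fit`), `skipped` (data frame), `subtypes`, `h`.
#' @export
fit_all <- function(expr, meth, pc, sa, sk, genes = colnames(expr),
                    nfolds = 5, seed = 1, lambda = NULL,
                    include_self = TRUE, intercept = TRUE, standardize = TRUE,
                    rule = c("min", "1se")) {
  built <- build_all_designs(expr, meth, pc, genes, include_self)
  fits <- list()
  for (g in names(built$designs)) {
    for (s in sa$subtypes) {
      fits[[paste(g, s, sep = "|")]] <-
        fit_gene_for_subtype(built$designs[[g]], sk, sa, s, nfolds = nfolds,
                             seed = seed, lambda = lambda,
                             intercept = intercept, standardize = standardize,
                             rule = rule)
    }
  }
  structure(list(fits = fits, skipped = built$skipped,
                 subtypes = sa$subtypes, h = sk$h),
            class = "kwl_fits")
}

#' @export
print.kwl_fits <- function(x, ...) {
  cat(sprintf("kwl_fits: %d fits (%d skipped genes), h = %g\n",
              length(x$fits), nrow(x$skipped), x$h))
  invisible(x)
}

#' Long-form coefficient table
#'
#' One row per (target gene, subtype, feature) with the fitted coefficient;
#' by default only nonzero coefficients are kept, which is the edge list the
#' network stage consumes.
#'
#' @param x a `kwl_fits` object.
#' @param row.names,optional ignored (S3 signature).
#' @param nonzero_only drop zero coefficients? (default TRUE)
#' @param ... unused.
#' @return data frame with columns target_gene, subtype, feature, beta,
#'   lambda, h.
#' @export
as.data.frame.kwl_fits <- function(x, row.names = NULL, optional = FALSE,
                                   nonzero_only = TRUE, ...) {
  rows <- lapply(x$fits, function(f) {
    keep <- if (nonzero_only) f$beta != 0 else rep(TRUE, length(f$beta))
    if (!any(keep)) return(NULL)
    data.frame(target_gene = f$target_gene, subtype = f$subtype,
               feature = names(f$beta)[keep], beta = unname(f$beta[keep]),
               lambda = f$lambda, h = f$h, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(target_gene = character(), subtype = character(),
                      feature = character(), beta = numeric(),
                      lambda = numeric(), h = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$target_gene, out$subtype, out$feature), , drop = FALSE]
}

# Cross-validated target-subtype prediction error at a given weighting.
# The penalty is chosen per the weighted criterion (matching how lambda is
# selected at fit time), but the returned score is the held-out error on
# target-subtype samples only. Scoring on the weighted error would compare
# incommensurable quantities across bandwidths, because the weights - and
# hence the error measure itself - change with h.
.target_cv_score <- function(X, y, w, labels, target, nfolds = 5, seed = 1,
                             intercept = TRUE, standardize = TRUE) {
  lambda <- lambda_grid(X, y, w, intercept = intercept, standardize = standardize)
  folds <- make_folds(labels, nfolds, seed)
  L <- length(lambda)
  wsse <- numeric(L)
  wsum <- 0
  tsse <- numeric(L)
  tn <- 0
  for (f in sort(unique(folds))) {
    test <- folds == f
    fit <- fit_weighted_lasso_path(X[!test, , drop = FALSE], y[!test],
                                   w[!test], lambda,
                                   intercept = intercept, standardize = standardize)
    pred <- predict_lasso(fit$beta, fit$intercept, X[test, , drop = FALSE])
    err <- (y[test] - pred)^2
    wsse <- wsse + colSums(err * w[test])
    wsum <- wsum + sum(w[test])
    tt <- labels[test] == target
    if (any(tt)) {
      tsse <- tsse + colSums(err[tt, , drop = FALSE])
      tn <- tn + sum(tt)
    }
  }
  if (tn == 0) stop(sprintf("subtype '%s' absent from every test fold", target))
  cvm <- wsse / wsum
  i <- max(which(cvm <= min(cvm) + 1e-15))
  sqrt(tsse[i] / tn)
}

#' Select the kernel bandwidth by cross-validation
#'
#' Grid search over bandwidths. For each candidate `h`, every
#' (gene, subtype) pair is scored by cross-validation: models are fit on
#' training folds with the `h`-derived sample weights (penalty chosen by
#' the weighted criterion, as at fit time), and the score is the held-out
#' prediction RMSE on samples of the target subtype. The criterion is the
#' mean of these scores; the held-out measure is the same for every
#' candidate, so bandwidths are compared on equal footing. One global
#' bandwidth is chosen per run. Ties break toward the smaller bandwidth
#' (the more subtype-specific model).
#'
#' @param designs named list of [build_design()] results.
#' @param sa a [subtype_assignment()].
#' @param dist between-subtype distance matrix.
#' @param h_grid candidate bandwidths (default 10 log-spaced points,
#'   1e-2 to 1e2).
#' @param nfolds,seed,intercept,standardize passed to [select_lambda()].
#' @return list with `h` (selected), `h_grid`, `score` (mean CV-RMSE per
#'   candidate).
#' @export
select_bandwidth <- function(designs, sa, dist,
                             h_grid = 10^seq(-2, 2, length.out = 10),
                             nfolds = 5, seed = 1,
                             intercept = TRUE, standardize = TRUE) {
  if (!length(designs)) stop("no designs to score")
  score <- vapply(h_grid, function(h) {
    sk <- subtype_kernel(dist, h)
    errs <- c()
    for (d in designs) {
      labels <- unname(sa$labels[d$sample_ids])
      for (s in sa$subtypes) {
        w <- sample_weights_for_target(sk, sa, s, d$sample_ids)
        errs <- c(errs, .target_cv_score(d$X, d$y, w, labels, s,
                                         nfolds = nfolds, seed = seed,
                                         intercept = intercept,
                                         standardize = standardize))
      }
    }
    mean(errs)
  }, numeric(1))
  best <- which(score <= min(score) + 1e-15)
  list(h = h_grid[min(best)], h_grid = h_grid, score = score)
}
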