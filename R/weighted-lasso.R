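#' @useDynLib kwlasso, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Centre/standardise the design under observation weights and precompute the
# Gram pieces shared by the whole lambda path. Standardisation is to unit
# *weighted* variance so the penalty treats features comparably; coefficients
# are mapped back to the original scale afterwards.
.kwl_prepare <- function(X, y, weights, intercept, standardize) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("y length must match nrow(X)")
  if (length(weights) != n) stop("weights length must match nrow(X)")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (!any(weights > 0)) stop("all-zero weights")
  if (!all(is.finite(X)) || !all(is.finite(y)) || !all(is.finite(weights))) {
    stop("non-finite values in design, response or weights")
  }
  sw <- sum(weights)
  if (intercept) {
    xm <- colSums(X * weights) / sw
    ym <- sum(y * weights) / sw
  } else {
    xm <- numeric(ncol(X))
    ym <- 0
  }
  Xc <- sweep(X, 2, xm, "-")
  yc <- y - ym
  if (standardize) {
    scale <- sqrt(colSums(weights * Xc^2) / sw)
    scale[scale == 0] <- 1
  } else {
    scale <- rep(1, ncol(X))
  }
  Xs <- sweep(Xc, 2, scale, "/")
  XtWX <- crossprod(Xs * weights, Xs)
  XtWy <- as.vector(crossprod(Xs, weights * yc))
  list(XtWX = XtWX, XtWy = XtWy, xm = xm, ym = ym, scale = scale,
       feature_ids = colnames(X))
}

#' Largest penalty with an all-zero solution
#'
#' For the sum-of-squares weighted objective the coefficient vector is
#' exactly zero whenever `lambda >= 2 * max_j |sum_i w_i x_ij (y_i - ybar_w)|`
#' (computed on the same centred/standardised scale the solver uses).
#'
#' @inheritParams fit_weighted_lasso
#' @return the smallest lambda at which all coefficients are zero.
#' @export
lambda_max <- function(X, y, weights = rep(1, nrow(as.matrix(X))),
                       intercept = TRUE, standardize = TRUE) {
  prep <- .kwl_prepare(X, y, weights, intercept, standardize)
  2 * max(abs(prep$XtWy))
}

#' Log-spaced penalty grid
#'
#' From [lambda_max()] down `decades` orders of magnitude, `nlambda`
#' log-spaced values (descending, so path fits can warm-start).
#'
#' @inheritParams fit_weighted_lasso
#' @param nlambda number of grid points.
#' @param decades how many orders of magnitude below `lambda_max` to cover.
#' @return decreasing numeric vector of penalties.
#' @export
lambda_grid <- function(X, y, weights = rep(1, nrow(as.matrix(X))),
                        nlambda = 50, decades = 3,
                        intercept = TRUE, standardize = TRUE) {
  lmax <- lambda_max(X, y, weights, intercept, standardize)
  if (lmax <= 0) lmax <- 1e-3  # response orthogonal to every feature
  exp(seq(log(lmax), log(lmax) - decades * log(10), length.out = nlambda))
}

#' Fit the sample-weighted lasso
#'
#' Solves `argmin_beta sum_i w_i (y_i - beta0 - x_i' beta)^2 + lambda ||beta||_1`
#' by cyclic coordinate descent with covariance updates. The intercept is
#' unpenalized (fitted by weighted centring); features are standardised to
#' unit weighted variance by default, with coefficients returned on the
#' original scale. Setting all weights to 1 recovers the plain lasso, and
#' `lambda = 0` recovers weighted least squares (when the weighted design
#' has full rank).
#'
#' @param X numeric matrix (samples x features).
#' @param y numeric response vector.
#' @param weights nonnegative per-sample weights, at least one positive.
#' @param lambda nonnegative penalty (scalar here; see [fit_weighted_lasso_path()]).
#' @param intercept fit an unpenalized intercept? (default TRUE)
#' @param standardize standardise features to unit weighted variance before
#'   fitting? (default TRUE)
#' @param tol coordinate-descent convergence tolerance.
#' @param maxit maximum sweeps per penalty value.
#' @return list with `beta` (named coefficient vector, original scale),
#'   `intercept`, and `lambda`.
#' @export
fit_weighted_lasso <- function(X, y, weights = rep(1, nrow(as.matrix(X))),
                               lambda, intercept = TRUE, standardize = TRUE,
                               tol = 1e-10, maxit = 100000L) {
  if (length(lambda) != 1 || lambda < 0) stop("lambda must be a single nonnegative value")
  path <- fit_weighted_lasso_path(X, y, weights, lambda, intercept,
                                  standardize, tol, maxit)
  list(beta = path$beta[, 1], intercept = path$intercept[1], lambda = lambda)
}

#' Fit the weighted lasso along a penalty path
#'
#' Same objective as [fit_weighted_lasso()] over a decreasing sequence of
#' penalties, with warm starts. The per-sample Gram matrices are computed
#' once per call, so a full path costs little more than a single fit.
#'
#' @inheritParams fit_weighted_lasso
#' @param lambda decreasing vector of nonnegative penalties.
#' @return list with `beta` (features x lambda matrix, original scale),
#'   `intercept` (vector), and `lambda`.
#' @export
fit_weighted_lasso_path <- function(X, y, weights = rep(1, nrow(as.matrix(X))),
                                    lambda, intercept = TRUE, standardize = TRUE,
                                    tol = 1e-10, maxit = 100000L) {
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  if (is.unsorted(rev(lambda), strictly = FALSE)) {
    stop("lambda must be non-increasing (warm starts run from large to small)")
  }
  prep <- .kwl_prepare(X, y, weights, intercept, standardize)
  B <- cd_lasso_cov(prep$XtWX, prep$XtWy, as.numeric(lambda), tol, as.integer(maxit))
  B <- B / prep$scale
  rownames(B) <- prep$feature_ids
  b0 <- as.vector(prep$ym - crossprod(prep$xm, B))
  if (!intercept) b0 <- rep(0, length(lambda))
  list(beta = B, intercept = b0, lambda = lambda)
}

#' Predict from a weighted-lasso fit
#' @param beta coefficient vector or matrix (features x lambda).
#' @param intercept scalar or vector of intercepts.
#' @param X new design matrix with matching columns.
#' @return vector (or matrix, one column per lambda) of predictions.
#' @export
predict_lasso <- function(beta, intercept, X) {
  X <- as.matrix(X)
  if (is.matrix(beta)) {
    sweep(X %*% beta, 2, -intercept, "-")
  } else {
    as.vector(X %*% beta) + intercept
  }
}
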