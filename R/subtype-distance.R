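#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum absolute difference between the empirical CDFs of `a` and
#' `b`. Distribution-free and in \[0, 1\]; identical samples give 0 and
#' samples with disjoint supports give 1. Ties are handled exactly by
#' evaluating the ECDF difference only where the pooled sorted values change.
#'
#' @param a,b numeric vectors, each with at least one finite value.
#' @return the KS statistic, a number in \[0, 1\].
#' @export
ks_statistic <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("samples must be finite")
  n <- length(a)
  m <- length(b)
  pooled <- c(a, b)
  ord <- order(pooled)
  step <- ifelse(ord <= n, 1 / n, -1 / m)
  gap <- cumsum(step)
  sorted <- pooled[ord]
  at_jump <- c(diff(sorted) != 0, TRUE)  # ECDF difference only counts after ties resolve
  max(abs(gap[at_jump]))
}

#' Between-subtype KS distance matrix
#'
#' For each pair of subtypes, all methylation values of all samples in each
#' subtype are pooled into one empirical sample per subtype, and the distance
#' is the two-sample KS statistic between the two pools. Pooling makes the
#' distance invariant to sample order within a subtype and gives one ECDF
#' comparison per pair. With `scaled = TRUE` the statistic is additionally
#' multiplied by sqrt(nm/(n+m)) (the two-sample KS test-statistic scaling);
#' the unscaled statistic, which stays in \[0, 1\], is the default distance.
#'
#' @param meth an [omics_matrix()] of methylation values (typically the
#'   log-normalized, filtered matrix used for fitting).
#' @param sa a [subtype_assignment()] covering every sample of `meth`.
#' @param scaled multiply by the sample-size factor sqrt(nm/(n+m))?
#' @return a symmetric nonnegative matrix with zero diagonal, dimnames the
#'   subtype names.
#' @export
subtype_distance_matrix <- function(meth, sa, scaled = FALSE) {
  unlabeled <- setdiff(rownames(meth), names(sa$labels))
  if (length(unlabeled)) {
    stop(sprintf("samples without subtype label: %s",
                 paste(unlabeled, collapse = ", ")))
  }
  pools <- lapply(sa$subtypes, function(s) {
    ids <- names(sa$labels)[sa$labels == s]
    ids <- intersect(rownames(meth), ids)
    if (!length(ids)) stop(sprintf("subtype '%s' has no samples in the matrix", s))
    as.vector(unclass(meth)[ids, , drop = FALSE])
  })
  names(pools) <- sa$subtypes
  k <- length(pools)
  d <- matrix(0, k, k, dimnames = list(sa$subtypes, sa$subtypes))
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        dij <- ks_statistic(pools[[i]], pools[[j]])
        if (scaled) {
          n <- length(pools[[i]])
          m <- length(pools[[j]])
          dij <- dij * sqrt(n * m / (n + m))
        }
        d[i, j] <- d[j, i] <- dij
      }
    }
  }
  d
}

#' RBF kernel weight
#'
#' `K_h(d) = exp(-d^2 / h)`: maps a nonnegative distance to a weight in
#' (0, 1\]. The bandwidth `h` controls how fast the weight decays; as
#' `h -> Inf` all weights tend to 1 (pooled estimation) and as `h -> 0` all
#' off-zero distances get weight 0 (separate estimation).
#'
#' @param d nonnegative distance(s).
#' @param h positive bandwidth.
#' @return weight(s) in (0, 1\].
#' @export
rbf_weight <- function(d, h) {
  if (!is.numeric(h) || length(h) != 1 || !is.finite(h) || h <= 0) {
    stop("bandwidth h must be a positive number")
  }
  if (any(d < 0)) stop("distances must be nonnegative")
  exp(-d^2 / h)
}

#' Build a subtype kernel
#'
#' Couples a between-subtype distance matrix with a bandwidth, producing the
#' subtype-by-subtype weight matrix `K_h(dist)` used to weight samples in
#' the kernel-weighted lasso.
#'
#' @param dist symmetric nonnegative subtype distance matrix with zero
#'   diagonal (e.g. from [subtype_distance_matrix()]).
#' @param h positive bandwidth.
#' @return an object of class `subtype_kernel` with fields `subtypes`,
#'   `dist`, `h`, `weights`.
#' @export
subtype_kernel <- function(dist, h) {
  dist <- as.matrix(dist)
  if (is.null(rownames(dist)) || !identical(rownames(dist), colnames(dist))) {
    stop("dist must have matching subtype dimnames")
  }
  if (any(abs(dist - t(dist)) > 1e-12) || any(diag(dist) != 0) || any(dist < 0)) {
    stop("dist must be symmetric and nonnegative with zero diagonal")
  }
  w <- rbf_weight(dist, h)
  diag(w) <- 1
  structure(list(subtypes = rownames(dist), dist = dist, h = h, weights = w),
            class = "subtype_kernel")
}

#' @export
print.subtype_kernel <- function(x, ...) {
  cat(sprintf("subtype_kernel: %d subtypes, h = %g\n", length(x$subtypes), x$h))
  print(round(x$weights, 4))
  invisible(x)
}

#' Per-sample weights for a target subtype
#'
#' Every sample contributes to the target subtype's fit; a sample of subtype
#' `s` gets weight `K_h(dist(s, target))`, so target-subtype samples get
#' exactly 1 and more distant subtypes contribute less.
#'
#' @param sk a [subtype_kernel()].
#' @param sa a [subtype_assignment()].
#' @param target_subtype one of `sk$subtypes`.
#' @param sample_ids which samples (default all labeled samples, in label
#'   order).
#' @return named numeric vector of weights in (0, 1\].
#' @export
sample_weights_for_target <- function(sk, sa, target_subtype,
                                      sample_ids = names(sa$labels)) {
  if (!target_subtype %in% sk$subtypes) {
    stop(sprintf("unknown subtype '%s'", target_subtype))
  }
  lab <- sa$labels[sample_ids]
  if (anyNA(lab)) stop("sample without subtype label")
  stats::setNames(sk$weights[target_subtype, lab], sample_ids)
}

#' Export a subtype matrix (distances or weights) as TSV
#' @param m square matrix with subtype dimnames.
#' @param path output path.
#' @export
write_subtype_matrix <- function(m, path) {
  header <- paste(c("subtype", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], formatC(m[i, ], digits = 12, format = "g")),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a subtype matrix written by [write_subtype_matrix()]
#' @param path path to the TSV.
#' @return a square numeric matrix with subtype dimnames.
#' @export
load_subtype_matrix <- function(path) {
  m <- load_matrix(path)
  out <- unclass(m)
  out
}
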