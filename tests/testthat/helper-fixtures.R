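# Small shared fixtures, built in code at load time.

om <- function(values, samples = NULL, features = NULL) {
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(values)))
  if (is.null(features)) features <- paste0("f", seq_len(ncol(values)))
  omics_matrix(matrix(as.numeric(values), nrow(values), ncol(values)),
               samples, features)
}

# a tiny processed bundle used across fit/evaluation/network tests
tiny_bundle <- function(seed = 11) {
  cfg <- sim_config(n_per_subtype = c(A = 10, B = 14, C = 8, D = 12),
                    p_features = 16, n_genes = 4, n_pathways = 2,
                    shared_support_size = 2, specific_support_size = 1,
                    seed = seed)
  b <- generate(cfg)
  b$expr_log <- log_normalize(b$expr)
  b$meth_log <- log_normalize(b$meth)
  b$dist <- subtype_distance_matrix(b$meth_log, b$sa)
  b
}

# brute-force two-sample KS oracle: evaluate both ECDFs at every pooled point
ks_brute <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(grid, function(x) mean(b <= x), numeric(1))
  max(abs(Fa - Fb))
}

# independent weighted-lasso oracle: glmnet on sqrt(w)-scaled centred rows
glmnet_oracle <- function(X, y, w, lambda) {
  sw <- sum(w)
  xm <- colSums(X * w) / sw
  ym <- sum(y * w) / sw
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  fit <- glmnet::glmnet(Xc * sqrt(w), yc * sqrt(w), intercept = FALSE,
                        standardize = FALSE, lambda = lambda / (2 * nrow(X)),
                        thresh = 1e-18, maxit = 1e7)
  as.vector(fit$beta)
}
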