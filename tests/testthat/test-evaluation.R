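test_that("constant responses give zero cross-validated error", {
  b <- tiny_bundle()
  dsg <- build_design("TG01", b$expr_log, b$meth_log, b$pc)
  dsg$y[] <- 3.14
  sk <- subtype_kernel(b$dist, 0.5)
  recs <- cv_rmse(dsg, b$sa, sk, seed = 1)
  expect_true(all(recs$rmse < 1e-10))
  expect_true(all(recs$n_test >= 1))
})

test_that("zero distances make kernel-weighted and pooled estimates identical", {
  b <- tiny_bundle()
  dsg <- build_design("TG02", b$expr_log, b$meth_log, b$pc)
  sk0 <- subtype_kernel(b$dist * 0, 1)
  recs <- cv_rmse(dsg, b$sa, sk0, methods = c("kernel_weighted", "pooled"),
                  seed = 4)
  kw <- recs[recs$method == "kernel_weighted", ]
  po <- recs[recs$method == "pooled", ]
  m <- merge(kw, po, by = "subtype")
  expect_equal(m$rmse.x, m$rmse.y, tolerance = 1e-8)
})

test_that("per-subtype squared errors pool to the overall error", {
  b <- tiny_bundle()
  dsg <- build_design("TG01", b$expr_log, b$meth_log, b$pc)
  sk <- subtype_kernel(b$dist, 1)
  recs <- cv_rmse(dsg, b$sa, sk, methods = "pooled", seed = 7)
  # conservation: total SSE = sum over subtypes of n_test * rmse^2
  total_sse <- sum(recs$n_test * recs$rmse^2)
  n_total <- sum(recs$n_test)
  expect_identical(n_total, length(dsg$y))
  # recompute overall pooled RMSE directly from a manual outer CV
  labels <- unname(b$sa$labels[dsg$sample_ids])
  folds <- make_folds(labels, 5, seed = 7)
  sse <- 0
  for (f in sort(unique(folds))) {
    test <- folds == f
    sel <- select_lambda(dsg$X[!test, ], dsg$y[!test], labels = labels[!test],
                         seed = 7 + 1000L * f)
    fit <- fit_weighted_lasso(dsg$X[!test, ], dsg$y[!test], lambda = sel$lambda)
    pred <- predict_lasso(fit$beta, fit$intercept, dsg$X[test, , drop = FALSE])
    sse <- sse + sum((dsg$y[test] - pred)^2)
  }
  expect_equal(total_sse, sse, tolerance = 1e-10)
})

test_that("cv_rmse is deterministic and covers every subtype and method", {
  b <- tiny_bundle()
  dsg <- build_design("TG04", b$expr_log, b$meth_log, b$pc)
  sk <- subtype_kernel(b$dist, 0.5)
  r1 <- cv_rmse(dsg, b$sa, sk, seed = 3)
  r2 <- cv_rmse(dsg, b$sa, sk, seed = 3)
  expect_identical(r1, r2)
  expect_identical(sort(unique(r1$method)),
                   c("kernel_weighted", "pooled", "separate"))
  expect_identical(sort(unique(r1$subtype)), c("A", "B", "C", "D"))
})

test_that("gene rankings sort by error and by improvement with ID tie-breaks", {
  recs <- expand.grid(target_gene = c("g1", "g2", "g3"),
                      subtype = c("S1", "S2"),
                      method = c("kernel_weighted", "pooled"),
                      stringsAsFactors = FALSE)
  rmse_map <- c(g1 = 0.1, g2 = 0.2, g3 = 0.3)
  recs$rmse <- rmse_map[recs$target_gene]
  recs$rmse[recs$method == "pooled"] <- recs$rmse[recs$method == "pooled"] +
    c(g1 = 0.05, g2 = 0, g3 = 0.2)[recs$target_gene[recs$method == "pooled"]]
  recs$n_test <- 5L
  rk <- rank_genes(recs)
  expect_identical(rk$overall$gene, c("g1", "g2", "g3"))
  # per-subtype: improvement (pooled - kernel) descending; zero ranks below positive
  expect_identical(rk$by_subtype$S1$gene, c("g3", "g1", "g2"))
  expect_equal(rk$by_subtype$S1$improvement, c(0.2, 0.05, 0))

  # random records: order agrees with an independent sort oracle
  set.seed(31)
  rr <- data.frame(target_gene = rep(paste0("G", 1:12), each = 2),
                   subtype = rep(c("X", "Y"), 12),
                   method = "kernel_weighted",
                   rmse = runif(24), n_test = 4L, stringsAsFactors = FALSE)
  rk2 <- rank_genes(rr)
  oracle <- tapply(rr$rmse, rr$target_gene, mean)
  oracle <- oracle[order(unname(oracle), names(oracle))]
  expect_identical(rk2$overall$gene, names(oracle))
  expect_equal(rk2$overall$rmse, as.numeric(oracle))
})

test_that("pathway scores sum member-gene errors, once per containing pathway", {
  recs <- data.frame(target_gene = c("g1", "g2", "g3"),
                     subtype = "S", method = "kernel_weighted",
                     rmse = c(0.1, 0.2, 0.4), n_test = 5L,
                     stringsAsFactors = FALSE)
  pc <- pathway_collection(list(P1 = c("g1", "g2"), P2 = "g3"))
  ps <- pathway_error(recs, pc)
  expect_equal(ps$score[ps$pathway == "P1"], 0.3)
  # disjoint pathways partitioning all genes: scores sum to the total error
  expect_equal(sum(ps$score), sum(recs$rmse))

  # overlapping pathways: each gene counted once per containing pathway
  set.seed(32)
  genes <- paste0("g", 1:10)
  recs2 <- data.frame(target_gene = genes, subtype = "S",
                      method = "kernel_weighted", rmse = runif(10),
                      n_test = 3L, stringsAsFactors = FALSE)
  sets <- lapply(1:4, function(i) sample(genes, sample(3:6, 1)))
  names(sets) <- paste0("P", 1:4)
  pc2 <- pathway_collection(sets)
  ps2 <- pathway_error(recs2, pc2)
  err <- stats::setNames(recs2$rmse, recs2$target_gene)
  for (p in names(sets)) {
    direct <- 0
    for (g in genes) for (s in sets[[p]]) if (g == s) direct <- direct + err[g]
    expect_equal(ps2$score[ps2$pathway == p], unname(direct))
  }

  # pathway with no scored genes is dropped with a warning
  pc3 <- pathway_collection(list(P1 = c("g1", "g2"), P_none = "absent"))
  expect_warning(ps3 <- pathway_error(recs, pc3), "P_none")
  expect_false("P_none" %in% ps3$pathway)
})

test_that("improvement-based pathway scores use the chosen subtype", {
  recs <- expand.grid(target_gene = c("g1", "g2"), subtype = c("S1", "S2"),
                      method = c("kernel_weighted", "pooled"),
                      stringsAsFactors = FALSE)
  recs$rmse <- c(0.1, 0.3, 0.2, 0.4,   # kernel S1, S1, S2, S2 (g1,g2 pairs)
                 0.3, 0.4, 0.2, 0.5)
  recs$n_test <- 4L
  pc <- pathway_collection(list(P = c("g1", "g2")))
  ps <- pathway_error(recs, pc, statistic = "improvement", subtype = "S1")
  imp <- (0.3 - 0.1) + (0.4 - 0.3)
  expect_equal(ps$score, imp)
  expect_error(pathway_error(recs, pc, statistic = "improvement"), "subtype")
})
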