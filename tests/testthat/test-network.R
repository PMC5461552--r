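fits_table <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

test_that("networks contain one edge per sufficiently nonzero coefficient", {
  tab <- fits_table(target_gene = "g1", subtype = "S1",
                    feature = c("f1", "f2", "f3"), beta = c(0.5, 0, -0.2))
  net <- build_networks(tab)
  expect_identical(nrow(net$edges), 2L)
  expect_setequal(net$edges$feature, c("f1", "f3"))

  empty <- build_networks(fits_table(target_gene = "g1", subtype = "S1",
                                     feature = "f1", beta = 0))
  expect_identical(nrow(empty$edges), 0L)
  expect_error(build_networks(tab, tolerance = 0), "positive")

  # random sparse collection: per-subtype counts equal an nnz oracle
  set.seed(40)
  tab2 <- expand.grid(target_gene = paste0("g", 1:6),
                      subtype = c("S1", "S2", "S3"),
                      feature = paste0("f", 1:8), stringsAsFactors = FALSE)
  tab2$beta <- rnorm(nrow(tab2)) * rbinom(nrow(tab2), 1, 0.3)
  net2 <- build_networks(tab2, tolerance = 0.05)
  for (s in c("S1", "S2", "S3")) {
    expect_identical(sum(net2$edges$subtype == s),
                     sum(abs(tab2$beta[tab2$subtype == s]) > 0.05))
  }
})

test_that("venn partition classifies edges by exact membership and conserves counts", {
  # identical networks across 4 subtypes: everything in the all-subtype cell
  base <- expand.grid(target_gene = paste0("g", 1:3), feature = paste0("f", 1:4),
                      stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(c("S1", "S2", "S3", "S4"), function(s) {
    cbind(base, subtype = s, beta = 1)
  }))
  vp <- venn_partition(build_networks(tab))
  expect_identical(nrow(vp$cells), 1L)
  expect_identical(vp$cells$n_members, 4L)
  expect_identical(vp$cells$count, 12L)
  expect_identical(sum(vp$cells$count), vp$n_union)

  # disjoint networks: every edge subtype-specific, union = sum of sizes
  tab2 <- fits_table(target_gene = rep(paste0("g", 1:4), each = 2),
                     subtype = rep(c("S1", "S2", "S3", "S4"), each = 2),
                     feature = paste0("f", 1:8), beta = 1)
  net2 <- build_networks(tab2)
  vp2 <- venn_partition(net2)
  expect_true(all(vp2$assignment$n_members == 1))
  expect_identical(vp2$n_union, 8L)
  expect_identical(nrow(subtype_specific_edges(net2)), 8L)
})

test_that("venn cells match a brute-force enumeration over 1000 random edges", {
  set.seed(41)
  subtypes <- c("A", "B", "C", "D")
  edges <- data.frame(feature = paste0("f", 1:1000),
                      gene = sample(paste0("g", 1:50), 1000, replace = TRUE),
                      stringsAsFactors = FALSE)
  membership <- lapply(1:1000, function(i) {
    subtypes[as.logical(rbinom(4, 1, 0.4))]
  })
  keep <- lengths(membership) > 0
  edges <- edges[keep, ]; membership <- membership[keep]
  tab <- do.call(rbind, lapply(seq_len(nrow(edges)), function(i) {
    data.frame(target_gene = edges$gene[i], subtype = membership[[i]],
               feature = edges$feature[i], beta = 1, stringsAsFactors = FALSE)
  }))
  net <- build_networks(tab)
  net$subtypes <- subtypes
  vp <- venn_partition(net)
  # enumeration oracle over all 15 nonempty subsets
  oracle <- table(vapply(membership, paste, character(1), collapse = "|"))
  for (cell in names(oracle)) {
    expect_identical(vp$cells$count[vp$cells$members == cell],
                     as.integer(oracle[[cell]]))
  }
  expect_identical(sum(vp$cells$count), vp$n_union)
  expect_identical(vp$n_union, nrow(edges))
})

test_that("hub degrees count subtype-specific edges with per-subtype breakdown", {
  # star: one methylation feature linked to 9 genes in one subtype
  tab <- fits_table(target_gene = paste0("g", 1:9), subtype = "S1",
                    feature = "LEPlike", beta = 1)
  tab <- rbind(tab, fits_table(target_gene = "g1", subtype = "S2",
                               feature = "other", beta = 1))
  net <- build_networks(tab)
  hubs <- hub_degrees(net, "methylation")
  expect_identical(hubs$node[1], "LEPlike")
  expect_identical(hubs$total[1], 9L)
  # row-sum consistency: total equals the sum of per-subtype degrees
  expect_identical(hubs$total, hubs$S1 + hubs$S2)

  expect_identical(nrow(hub_degrees(build_networks(
    fits_table(target_gene = "g", subtype = "S", feature = "f", beta = 0)),
    "methylation")), 0L)
})

test_that("degrees match an adjacency row-sum oracle on random bipartite networks", {
  set.seed(42)
  tab <- expand.grid(target_gene = paste0("g", 1:10),
                     subtype = c("S1", "S2", "S3"),
                     feature = paste0("f", 1:6), stringsAsFactors = FALSE)
  tab$beta <- rnorm(nrow(tab)) * rbinom(nrow(tab), 1, 0.25)
  net <- build_networks(tab)
  full <- hub_degrees(net, "methylation", specific_only = FALSE)
  adj <- table(net$edges$feature)
  for (i in seq_len(nrow(full))) {
    expect_identical(full$total[i], as.integer(adj[[full$node[i]]]))
  }
  # bipartite: methylation-side degrees and expression-side degrees both sum
  # to the edge count
  expr_side <- hub_degrees(net, "expression", specific_only = FALSE)
  expect_identical(sum(full$total), nrow(net$edges))
  expect_identical(sum(expr_side$total), nrow(net$edges))
})

test_that("edge-list export round-trips and formats are well-formed", {
  tab <- fits_table(target_gene = c("g1", "g2"), subtype = c("S1", "S2"),
                    feature = c("f1", "f2"), beta = c(0.5, -0.25))
  net <- build_networks(tab)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  expect_identical(length(readLines(tsv)), 3L)  # header + 2 edges
  back <- load_network(tsv)
  expect_equal(back$edges[, c("feature", "gene", "subtype", "beta")],
               net$edges[, c("feature", "gene", "subtype", "beta")],
               tolerance = 1e-10)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  expect_identical(readLines(sif)[1], "f1\tmeth_assoc_S1\tg1")

  expect_error(export_network(net, tsv, "dot"), "arg")
})

test_that("GraphML export is readable by an independent parser", {
  tab <- fits_table(target_gene = rep(c("g1", "g2"), 2),
                    subtype = rep(c("S1", "S2"), each = 2),
                    feature = rep(c("f1", "f2"), 2), beta = 0.7)
  net <- build_networks(tab)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(as.integer(igraph::vcount(g)), 4L)  # 2 features + 2 genes
  expect_equal(as.integer(igraph::ecount(g)), nrow(net$edges))
  expect_setequal(unique(igraph::V(g)$role), c("methylation", "expression"))
  expect_setequal(unique(igraph::E(g)$subtype), c("S1", "S2"))
})
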