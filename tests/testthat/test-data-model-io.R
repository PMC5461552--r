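test_that("matrix TSV round-trips exactly and respects orientation", {
  m <- om(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path)
  back <- load_matrix(path)
  expect_identical(unclass(back), unclass(m))

  flipped <- load_matrix(path, "samples_in_columns")
  expect_identical(unclass(flipped), t(unclass(m)))

  # full-precision round trip on irrational values
  m2 <- om(matrix(c(pi, exp(1), sqrt(2), 1/3), 2, 2))
  write_matrix(m2, path)
  expect_equal(unclass(load_matrix(path)), unclass(m2), tolerance = 1e-11)
})

test_that("malformed matrix files are rejected with coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("sample_id\tg1\tg1", "s1\t1\t2", "s2\t3\t4"), path)
  expect_error(load_matrix(path), "g1")

  writeLines(c("sample_id\tg1\tg2", "s1\t1\tx", "s2\t3\t4"), path)
  expect_error(load_matrix(path), "'x'.*'s1'.*'g2'")

  writeLines(c("sample_id\tg1\tg2", "s1\t1\tNA", "s2\t3\t4"), path)
  expect_error(load_matrix(path), "missing value")

  writeLines(c("sample_id\tg1\tg2", "s1\t1\t2", "s1\t3\t4"), path)
  expect_error(load_matrix(path), "duplicate sample")
})

test_that("omics_matrix enforces its invariants", {
  expect_error(om(matrix(c(1, NA, 3, 4), 2, 2)), "missing value")
  v <- matrix(1:4, 2, 2)
  expect_error(omics_matrix(v, c("s1", "s1"), c("f1", "f2")), "duplicate")
  expect_error(omics_matrix(v, c("s1", "s2"), c("f1", "")), "empty or missing")
})

test_that("log_normalize applies log(T+1) and preserves ordering", {
  m <- om(matrix(c(0, exp(1) - 1, 9, 0), 2, 2))
  out <- log_normalize(m)
  expect_equal(unclass(out)[1, 1], 0)
  expect_equal(unclass(out)[2, 1], 1)  # column-major: e-1 sits at [2,1]
  expect_equal(unclass(log_normalize(om(matrix(0, 3, 2)))),
               unclass(om(matrix(0, 3, 2))))
  expect_error(log_normalize(om(matrix(c(-1, 1, 2, 3), 2, 2))), "negative")

  # strict monotonicity entrywise: ordering of any two entries is preserved
  set.seed(1)
  vals <- matrix(rexp(60), 10, 6)
  tr <- unclass(log_normalize(om(vals)))
  expect_identical(order(as.vector(vals)), order(as.vector(tr)))
})

test_that("zero-heavy filter drops columns with strictly more than half zeros", {
  vals <- cbind(c(0, 0, 0, 1, 2, 3),   # exactly half: kept
                c(0, 0, 0, 0, 2, 3),   # 4/6: dropped
                c(1, 2, 3, 4, 5, 6))
  out <- filter_zero_heavy(om(vals))
  expect_identical(colnames(out), c("f1", "f3"))

  # planted-zero counting oracle on a larger random matrix
  set.seed(42)
  vals <- matrix(rexp(20 * 50), 20, 50)
  zero_n <- sample(0:20, 50, replace = TRUE)
  for (j in 1:50) vals[seq_len(zero_n[j]), j] <- 0
  m <- om(vals)
  kept <- colnames(filter_zero_heavy(m))
  oracle <- colnames(m)[colSums(unclass(m) == 0) / 20 <= 0.5]
  expect_identical(kept, oracle)
})

test_that("pathway-membership filter keeps member columns and is idempotent", {
  m <- om(matrix(1:15, 3, 5), features = c("a", "b", "c", "d", "e"))
  pc <- pathway_collection(list(P1 = c("a", "c"), P2 = c("c", "e", "zz")))
  out <- filter_by_pathway_membership(m, pc)
  expect_identical(colnames(out), c("a", "c", "e"))
  expect_identical(unclass(filter_by_pathway_membership(out, pc)), unclass(out))

  pc_all <- pathway_collection(list(P = c("a", "b", "c", "d", "e")))
  expect_identical(unclass(filter_by_pathway_membership(m, pc_all)), unclass(m))

  pc_none <- pathway_collection(list(P = "other_gene"))
  expect_error(filter_by_pathway_membership(m, pc_none), "no features remain")
})

test_that("probe collapse keeps the probe least correlated with expression", {
  set.seed(3)
  e <- rnorm(12)
  expr <- om(matrix(e, 12, 1), features = "G1")
  meth <- om(cbind(-e, e, rnorm(12)), features = c("p_neg", "p_pos", "p_noise"))
  pm <- probe_map(c("p_neg", "p_pos", "p_noise"), c("G1", "G1", "G1"))
  out <- collapse_probes(meth, expr, pm)
  expect_identical(colnames(out), "G1")
  expect_equal(unname(unclass(out)[, 1]), -e)  # the r = -1 probe

  # min |r| rule picks the uncorrelated probe instead
  out2 <- collapse_probes(meth, expr, pm, rule = "min_abs")
  expect_equal(unname(unclass(out2)[, 1]), unname(unclass(meth)[, "p_noise"]))

  # single probe kept regardless of correlation
  pm1 <- probe_map("p_pos", "G1")
  out3 <- collapse_probes(meth, expr, pm1)
  expect_equal(unname(unclass(out3)[, 1]), e)
})

test_that("probe collapse matches a direct Pearson arg-min oracle", {
  set.seed(9)
  n <- 15
  expr <- om(matrix(rnorm(n), n, 1), features = "G")
  probes <- paste0("pr", 1:6)
  meth <- om(matrix(rnorm(n * 6), n, 6), features = probes)
  pm <- probe_map(probes, rep("G", 6))
  out <- collapse_probes(meth, expr, pm)
  r <- vapply(probes, function(p) {
    x <- unclass(meth)[, p]; y <- unclass(expr)[, 1]
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }, numeric(1))
  expect_equal(unname(unclass(out)[, "G"]),
               unname(unclass(meth)[, probes[which.min(r)]]))
})

test_that("probe collapse warns and drops genes without expression", {
  set.seed(5)
  expr <- om(matrix(rnorm(8), 8, 1), features = "G1")
  meth <- om(matrix(rnorm(16), 8, 2), features = c("p1", "p2"))
  pm <- probe_map(c("p1", "p2"), c("G1", "G_absent"))
  expect_warning(out <- collapse_probes(meth, expr, pm), "G_absent")
  expect_identical(colnames(out), "G1")
})

test_that("GMT files parse with set semantics and round-trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("P1\tdesc\tA\tB", "P2\tother\tB\tB\tC"), path)
  pc <- load_gmt(path)
  expect_setequal(pc$sets$P1, c("A", "B"))
  expect_setequal(pc$sets$P2, c("B", "C"))  # duplicate stored once
  expect_identical(unname(pc$descriptions["P1"]), "desc")

  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(pc, out)
  expect_identical(load_gmt(out)$sets, pc$sets)

  writeLines(c("P1\tdesc"), path)
  expect_error(load_gmt(path), "fewer than 3 fields")
})

test_that("label tables parse with counts and reject bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tX", "s2\tX", "s3\tY", "s4\tY", "s5\tY",
               "s6\tZ", "s7\tZ", "s8\tZ", "s9\tZ"), path)
  sa <- load_labels(path)
  expect_identical(unname(sa$counts[c("X", "Y", "Z")]), c(2L, 3L, 4L))
  expect_identical(sum(sa$counts), 9L)

  # header auto-detection
  writeLines(c("sample_id\tsubtype", "s1\tX", "s2\tX", "s3\tY", "s4\tY"), path)
  expect_identical(length(load_labels(path)$labels), 4L)

  writeLines(c("s1\tX", "s2"), path)
  expect_error(load_labels(path), "fewer than 2 fields")

  expect_error(subtype_assignment(c(s1 = "X", s2 = "")), "empty subtype")
  expect_error(subtype_assignment(c(s1 = "X", s2 = "X", s3 = "Y")),
               "fewer than 2 samples")
})

test_that("probe maps load and enforce one gene per probe", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tgene_id", "p1\tG1", "p2\tG1", "p3\tG2"), path)
  pm <- load_probe_map(path)
  expect_identical(nrow(pm), 3L)
  expect_error(probe_map(c("p1", "p1"), c("G1", "G2")), "duplicate")
})
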