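test_that("fpkm_to_tpm rescales each sample to one million", {
  m <- make_expr(matrix(7, 1, 1), scale = "linear_fpkm")
  expect_equal(unname(as.vector(fpkm_to_tpm(m))), 1e6)

  m2 <- make_expr(matrix(c(1, 3), 2, 1), scale = "linear_fpkm")
  expect_equal(unname(as.vector(fpkm_to_tpm(m2))), c(250000, 750000))

  set.seed(4)
  r <- make_expr(matrix(stats::rexp(200), 20, 10), scale = "linear_fpkm")
  out <- fpkm_to_tpm(r)
  expect_equal(expr_scale(out), "linear_tpm")
  expect_true(all(abs(colSums(out) - 1e6) < 1e-6 * 1e6))
})

test_that("fpkm_to_tpm rejects all-zero samples by name", {
  m <- make_expr(cbind(a = c(1, 2), b = c(0, 0)), scale = "linear_fpkm",
                 samples = c("ok", "empty"))
  expect_error(fpkm_to_tpm(m), "empty")
  expect_error(fpkm_to_tpm(make_expr(matrix(1, 2, 2))), "linear_fpkm")
})

test_that("log2_transform is the documented monotone map and round-trips", {
  m <- make_expr(matrix(c(0, 3, 7, 15), 2, 2), scale = "linear_tpm")
  lg <- log2_transform(m, pseudocount = 1)
  expect_equal(unname(as.vector(lg)), c(0, 2, 3, 4))
  back <- 2^as.vector(lg) - 1
  expect_equal(back, c(0, 3, 7, 15), tolerance = 1e-10)
  expect_error(log2_transform(lg), "already")
  set.seed(1)
  r <- make_expr(matrix(stats::rexp(50), 10, 5), scale = "linear_tpm")
  expect_equal(unname(2^as.vector(log2_transform(r)) - 1),
               unname(as.vector(r)), tolerance = 1e-10)
})

test_that("quantile_normalize follows the sorted-mean rule and is idempotent", {
  m <- make_expr(cbind(c(1, 2, 3), c(4, 5, 6)), scale = "log2")
  qn <- quantile_normalize(m)
  expect_equal(unname(as.vector(qn)), c(2.5, 3.5, 4.5, 2.5, 3.5, 4.5))

  ident <- make_expr(cbind(c(1, 5, 2), c(1, 5, 2)), scale = "log2")
  expect_equal(as.vector(quantile_normalize(ident)), as.vector(ident))

  set.seed(2)
  r <- make_expr(matrix(stats::rnorm(60), 12, 5), scale = "log2")
  once <- quantile_normalize(r)
  twice <- quantile_normalize(once)
  expect_equal(as.vector(twice), as.vector(once), tolerance = 1e-10)

  single <- make_expr(matrix(1:3, 3, 1), scale = "log2")
  expect_warning(out <- quantile_normalize(single), "identity")
  expect_equal(as.vector(out), as.vector(single))
})

test_that("collapse_probes keeps the max-mean probe per feature", {
  m <- make_expr(rbind(c(5, 5), c(9, 9), c(1, 1)), scale = "log2",
                 features = c("p1", "p2", "p3"))
  pm <- data.frame(probe_id = c("p1", "p2", "p3"),
                   feature_id = c("lncA", "lncA", "lncB"))
  out <- collapse_probes(m, pm)
  expect_equal(nrow(out), 2L)
  expect_equal(as.vector(out["lncA", ]), c(9, 9))  # the mean-9 probe wins

  one2one <- data.frame(probe_id = c("p3", "p1", "p2"),
                        feature_id = c("f3", "f1", "f2"))
  perm <- collapse_probes(m, one2one)
  expect_setequal(rownames(perm), c("f1", "f2", "f3"))
  expect_equal(as.vector(perm["f2", ]), c(9, 9))

  expect_message(collapse_probes(m, pm[1:2, ]), "dropped")
  expect_error(collapse_probes(m, data.frame(probe_id = "zz", feature_id = "f")),
               "empty probe map")
})

test_that("intersect_features aligns on the common ordered set", {
  a <- make_expr(matrix(1:6, 3, 2), features = c("a", "b", "c"))
  b <- make_expr(matrix(1:6, 3, 2), features = c("b", "c", "d"))
  out <- intersect_features(a, b)
  expect_equal(rownames(out[[1]]), c("b", "c"))
  expect_equal(rownames(out[[2]]), c("b", "c"))

  same <- intersect_features(a, a)
  expect_equal(as.vector(same[[1]]), as.vector(a))

  # order invariance of the resulting feature set
  out_rev <- intersect_features(b, a)
  expect_setequal(rownames(out_rev[[1]]), rownames(out[[1]]))
  expect_error(intersect_features(a, make_expr(matrix(1, 1, 1), features = "zz")),
               "empty")
})

test_that("expression TSV round-trips with its scale header", {
  set.seed(3)
  m <- make_expr(matrix(stats::rnorm(20), 5, 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expr_tsv(m, path)
  expect_equal(readLines(path, n = 1L), "#scale=log2")
  back <- read_expr_tsv(path)
  expect_equal(as.vector(back), as.vector(m), tolerance = 1e-12)
  expect_equal(rownames(back), rownames(m))
  expect_equal(expr_scale(back), "log2")
})

test_that("matrices with missing or duplicate entries are rejected", {
  bad <- matrix(c(1, NA), 1, 2, dimnames = list("g", c("a", "b")))
  expect_error(expr_matrix(bad, "log2"), "missing")
  dup <- matrix(1:4, 2, 2, dimnames = list(c("g", "g"), c("a", "b")))
  expect_error(expr_matrix(dup, "log2"), "duplicate")
  neg <- matrix(-1, 1, 1, dimnames = list("g", "s"))
  expect_error(expr_matrix(neg, "linear_tpm"), "negative")
})
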