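test_that("clinical follow-up filters keep the 30-day boundary and count exclusions", {
  cl <- make_clinical(4, times = c(20, 30, 400, NA), status = c(1, 1, 0, 1))
  out <- filter_clinical_samples(cl)
  expect_equal(out$os_time, c(30, 400))
  ex <- attr(out, "exclusions")
  expect_equal(ex$n_excluded[ex$rule == "time_lt_30"], 1)
  expect_equal(ex$n_excluded[ex$rule == "unknown_time"], 1)

  ok <- make_clinical(5)
  kept <- filter_clinical_samples(ok)
  expect_equal(nrow(kept), 5)
  expect_true(all(attr(kept, "exclusions")$n_excluded == 0))

  mix <- make_clinical(10,
    times = c(5, 5, rep(100, 8)),
    status = c(1, 1, NA, NA, NA, 1, 1, 1, 1, 1))
  expect_equal(nrow(filter_clinical_samples(mix)), 5)

  expect_error(filter_clinical_samples(make_clinical(2, times = c(1, 2))),
               "no samples survive")
})

test_that("retained sample set is independent of row order", {
  cl <- make_clinical(8, times = c(10, NA, 31, 29, 100, NA, 30, 500),
                      status = c(1, 1, NA, 0, 1, NA, 0, 1))
  kept1 <- sort(filter_clinical_samples(cl)$sample_id)
  kept2 <- sort(filter_clinical_samples(cl[sample(8), ])$sample_id)
  expect_identical(kept1, kept2)
})

test_that("duplicate gene rows collapse to per-sample medians", {
  expr <- make_expr(matrix(c(1, 3, 3, 5), nrow = 2, byrow = TRUE),
                    genes = c("G", "G"), samples = c("s1", "s2"))
  out <- collapse_duplicate_genes(expr)
  expect_equal(out$gene, "G")
  expect_equal(unlist(out[1, -1], use.names = FALSE), c(2, 4))

  odd <- make_expr(matrix(c(1, 2, 9), ncol = 1), genes = rep("G", 3), samples = "s1")
  expect_equal(collapse_duplicate_genes(odd)$s1, 2)

  plain <- make_expr(matrix(1:6, nrow = 3))
  expect_equal(collapse_duplicate_genes(plain), plain, ignore_attr = TRUE)

  multi <- make_expr(matrix(1:4, nrow = 2), genes = c("A///B", "C"))
  out2 <- collapse_duplicate_genes(multi)
  expect_equal(out2$gene, "C")
  expect_equal(attr(out2, "n_multi_gene_rows"), 1)
})

test_that("cohort alignment intersects, sorts and logs both sides", {
  expr <- make_expr(matrix(1:6, nrow = 2), samples = c("b", "c", "a"))
  cl <- make_clinical(4, ids = c("c", "d", "a", "b"))
  b <- align_cohort(expr, cl)
  expect_equal(names(b$expression)[-1], c("a", "b", "c"))
  expect_equal(b$clinical$sample_id, c("a", "b", "c"))
  expect_equal(b$exclusion_log$n_dropped, c(0, 1))

  b2 <- align_cohort(expr[, c("gene", "a", "c", "b")], cl[c(3, 1, 4, 2), ])
  expect_identical(b$expression, b2$expression)
  expect_identical(b$clinical, b2$clinical)

  expect_error(align_cohort(expr, make_clinical(2, ids = c("x", "y"))),
               "no samples")

  sup <- align_cohort(make_expr(matrix(1:4, nrow = 2), samples = c("a", "b")), cl)
  expect_equal(nrow(sup$clinical), 2)
})

test_that("z-scoring uses the population SD and is idempotent", {
  expr <- make_expr(matrix(c(1, 2, 3), nrow = 1), samples = c("s1", "s2", "s3"))
  z <- zscore_genes(expr)
  expect_equal(unlist(z[1, -1], use.names = FALSE),
               c(-1.224744871, 0, 1.224744871), tolerance = 1e-8)

  again <- zscore_genes(z)
  expect_equal(as.matrix(again[-1]), as.matrix(z[-1]), tolerance = 1e-12)

  const <- make_expr(rbind(c(1, 2, 3), c(5, 5, 5)))
  expect_warning(zc <- zscore_genes(const), "zero-variance")
  expect_equal(nrow(zc), 1)
})

test_that("collapse then z-score commutes with sample permutation", {
  set.seed(1)
  m <- matrix(rnorm(24), nrow = 4)
  expr <- make_expr(m, genes = c("A", "B", "A", "C"))
  perm <- c(3, 1, 6, 2, 5, 4)
  ref <- zscore_genes(collapse_duplicate_genes(expr))
  permuted <- expr[, c(1, perm + 1)]
  out <- zscore_genes(collapse_duplicate_genes(permuted))
  expect_equal(as.matrix(out[-1]), as.matrix(ref[, c(1, perm + 1)][-1]),
               tolerance = 1e-12, ignore_attr = TRUE)
})
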