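test_that("the GSEA running sum matches a hand-walked toy", {
  st <- c(a = 4, b = 3, c = 2, d = 1)
  # single top-ranked hit, unweighted: +1 then three steps of -1/3
  res <- gsea_es(st, "a", weight_p = 0)
  expect_equal(res$es, 1)
  expect_equal(res$running_sum$running, c(1, 2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(res$leading_edge, "a")

  # whole list in the set
  expect_equal(gsea_es(st, letters[1:4])$es, 1)

  # weighted walk, hits at ranks 1 and 3: in-set weight total = 4 + 2
  res2 <- gsea_es(st, c("a", "c"), weight_p = 1)
  hand <- cumsum(c(4 / 6, -1 / 2, 2 / 6, -1 / 2))
  expect_equal(res2$running_sum$running, hand, tolerance = 1e-12)
  expect_equal(res2$es, hand[which.max(abs(hand))])

  expect_error(gsea_es(st, c("x", "y")), "no member")
})

test_that("unit weights reduce the weighted statistic to the classic KS walk", {
  set.seed(1)
  st <- setNames(rep(2, 30), paste0("g", 1:30))   # all-equal |stat|
  set <- paste0("g", sample(30, 8))
  expect_equal(gsea_es(st, set, weight_p = 1)$es,
               gsea_es(st, set, weight_p = 0)$es, tolerance = 1e-12)
})

test_that("gsea_run finds a planted set and is seed-deterministic", {
  set.seed(2)
  st <- setNames(sort(rnorm(200), decreasing = TRUE), paste0("g", 1:200))
  sets <- list(planted = paste0("g", 1:30),
               random = paste0("g", sample(200, 30)))
  res <- gsea_run(st, sets, n_perm = 200, seed = 5)
  planted <- res[res$set == "planted", ]
  expect_gt(planted$nes, 0)
  expect_lte(planted$p, 0.02)  # sign-conditioned null: ~n_perm/2 draws

  res2 <- gsea_run(st, sets, n_perm = 200, seed = 5)
  expect_identical(res, res2)
})

test_that("ORA p-values equal exact binomial-coefficient tail sums", {
  # saturated and empty overlaps
  uni <- paste0("g", 1:40)
  sets <- list(s1 = uni[1:8])
  full <- ora_hypergeometric(uni, sets, uni)
  expect_equal(full$overlap, 8)
  expect_equal(full$p, 1, tolerance = 1e-12)

  disjoint <- ora_hypergeometric(uni[31:40], list(s1 = uni[1:8]), uni)
  expect_equal(disjoint$overlap, 0)
  expect_equal(disjoint$p, 1, tolerance = 1e-12)

  # exact value: N=100, K=5, n=10, k=5
  uni2 <- paste0("g", 1:100)
  res <- ora_hypergeometric(uni2[1:10], list(s = uni2[6:10]), uni2)
  expect_equal(res$overlap, 5)
  expect_equal(res$p, hyper_tail_choose(5, 5, 100, 10), tolerance = 1e-14)

  # randomized spot-checks through the gene-list interface
  set.seed(3)
  for (i in 1:20) {
    N <- sample(10:30, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    u <- paste0("g", seq_len(N))
    res_i <- ora_hypergeometric(u[seq_len(n)], list(s = u[sample(N, K)]), u)
    expect_equal(res_i$p, hyper_tail_choose(res_i$overlap, K, N, n),
                 tolerance = 1e-12)
  }
})

test_that("signature scores reflect planted set activity", {
  set.seed(4)
  m <- matrix(rnorm(60 * 100), nrow = 60,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:100)))
  active <- 1:50
  m[1:10, active] <- m[1:10, active] + 1   # 1-SD shift of the set in half the cohort
  expr <- make_expr(m)
  sets <- list(sig = paste0("g", 1:10))

  for (meth in c("mean_z", "ssgsea")) {
    sc <- signature_score(expr, sets, method = meth)
    auc <- suppressWarnings(stats::wilcox.test(sc$sig[active], sc$sig[-active])$statistic /
                              (50 * 50))
    expect_gte(unname(auc), 0.95)
  }

  # single-gene set under mean_z is that gene's z-score
  one <- signature_score(expr, list(solo = "g60"), method = "mean_z")
  z <- (m["g60", ] - mean(m["g60", ])) / (sd(m["g60", ]) * sqrt(99 / 100))
  expect_equal(one$solo, unname(z), tolerance = 1e-12)

  # duplicated sample gets identical scores
  m2 <- m; m2[, 2] <- m2[, 1]
  sc2 <- signature_score(make_expr(m2), sets, method = "ssgsea")
  expect_equal(sc2$sig[1], sc2$sig[2], tolerance = 1e-12)
})

test_that("enrichment scores agree with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(5)
  st <- setNames(rnorm(150), paste0("g", 1:150))
  for (i in 1:5) {
    set <- paste0("g", sample(150, 20))
    sorted <- sort(st, decreasing = TRUE)
    expect_equal(gsea_es(st, set, weight_p = 1)$es,
                 fgsea::calcGseaStat(sorted, which(names(sorted) %in% set),
                                     gseaParam = 1),
                 tolerance = 1e-12)
  }
})
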