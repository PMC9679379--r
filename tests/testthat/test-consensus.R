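test_that("PAM separates well-separated clouds and handles degenerate k", {
  set.seed(1)
  x <- rbind(matrix(rnorm(10, 0, 0.1), 5), matrix(rnorm(10, 50, 0.1), 5))
  D <- as.matrix(dist(x))
  fit <- pam_cluster(D, 2)
  expect_equal(adjusted_rand_index(fit$clustering, rep(1:2, each = 5)), 1)

  all_own <- pam_cluster(D, nrow(D))
  expect_equal(all_own$cost, 0)
  expect_equal(sort(all_own$medoids), 1:10)

  expect_error(pam_cluster(D, 11), "k must be")
})

test_that("PAM matches exhaustive medoid search on a separable 8-point instance", {
  # three tight groups: PAM and brute force must agree exactly
  pts <- c(0, 0.1, 0.2, 10, 10.1, 20, 20.1, 20.2)
  D <- as.matrix(dist(pts))
  fit <- pam_cluster(D, 3)
  bf <- brute_force_pam(D, 3)
  expect_equal(fit$cost, bf$cost, tolerance = 1e-12)
  expect_equal(adjusted_rand_index(fit$clustering, bf$clustering), 1)
})

test_that("consensus matrices satisfy their invariants on arbitrary data", {
  set.seed(4)
  expr <- make_expr(matrix(rnorm(15 * 24), nrow = 15))
  cc <- consensus_cluster(expr, k_range = 2:3, reps = 30, seed = 99)
  for (M in cc$consensus) {
    expect_identical(M, t(M))
    expect_equal(diag(M), rep(1, ncol(M)), ignore_attr = TRUE)
    expect_true(all(M >= 0 & M <= 1))
  }
  expect_true(all(lengths(lapply(cc$assignments[-1], unique)) >= 2))

  cc2 <- consensus_cluster(expr, k_range = 2:3, reps = 30, seed = 99)
  expect_identical(cc$consensus, cc2$consensus)
  expect_identical(cc$assignments, cc2$assignments)
})

test_that("a single full-cohort resample reduces to one PAM co-membership matrix", {
  set.seed(5)
  expr <- make_expr(matrix(rnorm(10 * 12), nrow = 10))
  cc <- consensus_cluster(expr, k_range = 2, reps = 1, p_item = 1, seed = 3)
  z <- zscore_genes(expr)
  d <- methylscore:::sample_distance(z)
  cl <- pam_cluster(d, 2)$clustering
  expect_equal(unname(cc$consensus$k2), unname(outer(cl, cl, function(a, b) (a == b) * 1)))
})

test_that("insufficient resampling of pairs is refused with advice", {
  set.seed(6)
  expr <- make_expr(matrix(rnorm(5 * 20), nrow = 5))
  expect_error(consensus_cluster(expr, k_range = 2, reps = 1, p_item = 0.3, seed = 1),
               "increase")
})

test_that("planted three-cluster structure is recovered with high consensus", {
  co <- simulate_cohort(n_samples = 150, k_true = 3, cluster_shift = 2.0, seed = 11)
  panel <- co$truth_genes$gene[co$truth_genes$class == "regulator"]
  cc <- consensus_cluster(co$expression, features = panel, k_range = 3,
                          reps = 100, seed = 12)
  cl <- cc$assignments$k3
  expect_gte(adjusted_rand_index(cl, co$truth_samples$true_cluster), 0.95)
  M <- cc$consensus$k3
  within <- M[outer(cl, cl, "==") & upper.tri(M)]
  expect_gte(median(within), 0.9)
})

test_that("select_k recommends the planted k and flags structureless cohorts", {
  co <- simulate_cohort(n_samples = 120, k_true = 3, cluster_shift = 2.0, seed = 21)
  panel <- co$truth_genes$gene[co$truth_genes$class == "regulator"]
  cc <- consensus_cluster(co$expression, features = panel, k_range = 2:5,
                          reps = 60, seed = 22)
  sel <- select_k(cc)
  expect_equal(sel$chosen_k, 3)
  expect_false(sel$low_confidence)

  null_co <- simulate_cohort(n_samples = 80, k_true = 1, cluster_shift = 0,
                             n_deg_true = 0, surv_beta = 0, seed = 23)
  ncc <- consensus_cluster(null_co$expression, features = panel, k_range = 2:4,
                           reps = 60, seed = 24)
  nsel <- select_k(ncc)
  expect_true(nsel$low_confidence)
  # no clean split: ambiguity at k=2 far above the planted cohort's
  expect_gt(ncc$metrics$pac[ncc$metrics$k == 2], cc$metrics$pac[cc$metrics$k == 2])

  one <- consensus_cluster(co$expression, features = panel, k_range = 2,
                           reps = 30, seed = 25)
  expect_equal(select_k(one)$chosen_k, 2)
})
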