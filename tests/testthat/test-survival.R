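test_that("the product-limit curve matches hand-computed values", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-10)

  km2 <- km_estimate(c(1, 2, 3), c(0, 1, 1))
  expect_equal(km2$surv[km2$time == 2], 0.5, tolerance = 1e-10)
  expect_equal(km2$surv[km2$time == 3], 0, tolerance = 1e-10)

  km3 <- km_estimate(c(5, 8, 11), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
})

test_that("KM invariants and Greenwood variance hold on random data", {
  set.seed(2)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    km <- km_estimate(rexp(n, 0.01), rbinom(n, 1, 0.6))
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_true(all(km$surv >= 0 & km$surv <= 1))
    expect_true(all(km$greenwood_var >= 0))
    expect_equal(km$n_risk[1], n)
  }
})

test_that("median survival follows the S(t) <= 0.5 rule", {
  km <- tibble::tibble(time = c(10, 20, 30), surv = c(0.8, 0.5, 0.2))
  expect_equal(median_survival(km), 20)

  expect_true(is.na(median_survival(km_estimate(c(5, 8), c(0, 0)))))
  expect_equal(median_survival(km_estimate(5, 1)), 5)
})

test_that("log-rank reduces to zero on identical groups and matches hand tabulation", {
  t1 <- c(2, 4, 6, 8); s1 <- c(1, 0, 1, 1)
  lr0 <- logrank_test(c(t1, t1), c(s1, s1), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chi2, 0, tolerance = 1e-10)
  expect_equal(lr0$p, 1, tolerance = 1e-10)

  # 6-sample two-group case, O-E and V summed by hand over event times
  times <- c(1, 2, 3, 4, 5, 6); status <- c(1, 1, 1, 1, 0, 1)
  grp <- c("a", "b", "a", "b", "a", "b")
  o1 <- e1 <- v1 <- 0
  for (tt in times[status == 1]) {
    at <- times >= tt
    n <- sum(at); n1 <- sum(at & grp == "a")
    d <- sum(times == tt & status == 1)
    d1 <- sum(times == tt & status == 1 & grp == "a")
    o1 <- o1 + d1; e1 <- e1 + d * n1 / n
    if (n > 1) v1 <- v1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(logrank_test(times, status, grp)$chi2, (o1 - e1)^2 / v1,
               tolerance = 1e-10)

  # invariance under relabeling
  lr_ab <- logrank_test(times, status, grp)
  lr_ba <- logrank_test(times, status, ifelse(grp == "a", "b", "a"))
  expect_equal(lr_ab$chi2, lr_ba$chi2, tolerance = 1e-12)
})

test_that("three-group log-rank separates planted hazard groups", {
  set.seed(3)
  g <- rep(1:3, each = 40)
  tt <- rexp(120, rate = c(0.02, 0.01, 0.003)[g])
  lr <- logrank_test(tt, rep(1, 120), g)
  expect_equal(lr$df, 2)
  expect_lt(lr$p, 1e-4)
})

test_that("the cutpoint scan finds a perfectly separating gap", {
  score <- c(1:6, 101:106)
  times <- c(rep(5, 6), rep(500, 6))
  status <- c(rep(1, 6), rep(0, 6))
  cp <- find_cutpoint(score, times, status, minprop = 0.1)
  expect_gt(cp$cutpoint, 6)
  expect_lt(cp$cutpoint, 101)
  expect_equal(cp$n_low, 6)

  even <- find_cutpoint(rep(c(1, 2), 6), rexp(12), rbinom(12, 1, 0.9),
                        minprop = 0.5)
  expect_equal(nrow(even$scan), 1)
  expect_equal(even$cutpoint, 1.5)

  expect_error(find_cutpoint(rep(1, 10), rexp(10), rep(1, 10)), "identical")
})

test_that("the cutpoint equals an independent brute-force scan", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(15:30, 1)
    sc <- rnorm(n)
    tt <- rexp(n, exp(-0.5 * sc))
    ss <- rbinom(n, 1, 0.7)
    if (sum(ss) == 0) ss[1] <- 1
    cp <- find_cutpoint(sc, tt, ss, minprop = 0.1)
    bf <- brute_force_cutpoint(sc, tt, ss, minprop = 0.1)
    expect_equal(cp$cutpoint, bf$cutpoint, tolerance = 1e-10)
    expect_equal(cp$statistic, bf$statistic, tolerance = 1e-8)
  }
})

test_that("maximal selection inflates the statistic relative to a median split", {
  set.seed(5)
  n <- 24
  sel <- med <- numeric(80)
  for (i in seq_len(80)) {
    sc <- rnorm(n); tt <- rexp(n); ss <- rbinom(n, 1, 0.8)
    if (sum(ss) == 0) ss[1] <- 1
    cp <- find_cutpoint(sc, tt, ss, minprop = 0.1)
    sel[i] <- abs(cp$statistic)
    med[i] <- abs(methylscore:::logrank_z(tt, ss, sc > stats::median(sc)))
  }
  expect_gt(mean(sel), mean(med))
  expect_gt(mean(sel >= med), 0.9)
})

test_that("the permutation-adjusted p is more conservative than the naive p", {
  set.seed(6)
  n <- 30
  sc <- rnorm(n); tt <- rexp(n); ss <- rbinom(n, 1, 0.8)
  cp <- find_cutpoint(sc, tt, ss, n_perm = 99, seed = 7)
  expect_true(cp$selection_biased)
  expect_gte(cp$p_perm, cp$p_naive)
  expect_lte(cp$p_perm, 1)
})
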