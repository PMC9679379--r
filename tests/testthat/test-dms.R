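test_that("Cox screening flags degenerate genes and matches a grid-search oracle", {
  set.seed(1)
  n <- 20
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, exp(0.8 * x))
  ss <- rbinom(n, 1, 0.8)
  expr <- make_expr(rbind(g1 = x, flat = rep(2, n)))
  clin <- make_clinical(n, times = tt, status = ss)
  res <- suppressMessages(cox_screen(expr, clin, alpha = 1))
  expect_equal(res$status, c("ok", "constant"))

  # independent 1-D maximization of the Breslow partial likelihood
  breslow_ll <- function(b) {
    sum(vapply(which(ss == 1), function(i) {
      b * x[i] - log(sum(exp(b * x[tt >= tt[i]])))
    }, numeric(1)))
  }
  bhat <- stats::optimize(breslow_ll, c(-5, 5), maximum = TRUE, tol = 1e-9)$maximum
  expect_lt(abs(res$coef[1] - bhat), 1e-4)
})

test_that("screening enriches true prognostic genes and stays calibrated on nulls", {
  co <- simulate_cohort(n_samples = 150, k_true = 2, cluster_shift = 1.5,
                        n_background_genes = 400, n_deg_true = 50,
                        surv_beta = 1, seed = 3)
  truth <- co$truth_genes
  cand <- c(truth$gene[truth$class == "true_deg"],
            truth$gene[truth$class == "null"][1:200])
  res <- suppressMessages(cox_screen(co$expression, co$clinical, candidate_genes = cand))
  hit_deg <- mean(res$screened[match(truth$gene[truth$class == "true_deg"], res$gene)])
  hit_null <- mean(res$screened[match(truth$gene[truth$class == "null"][1:200], res$gene)])
  expect_gt(hit_deg, 5 * hit_null)
  expect_lt(hit_null, 0.12)
})

test_that("DMS is symmetric over duplicated samples and invariant to gene order", {
  set.seed(5)
  m <- matrix(rnorm(20 * 10), nrow = 20)
  m[, 10] <- m[, 9]                       # duplicated sample
  expr <- make_expr(m)
  genes <- expr$gene
  screen <- tibble::tibble(gene = genes[1:12],
                           hr = rep(c(0.7, 1.4), 6), screened = TRUE)
  fit <- fit_dms(expr, screen)
  expect_equal(fit$scores$dms[9], fit$scores$dms[10], tolerance = 1e-10)

  perm <- sample(nrow(expr))
  fit2 <- fit_dms(expr[perm, ], screen)
  expect_equal(fit$scores$dms, fit2$scores$dms, tolerance = 1e-10)

  # training-cohort invariants
  expect_lt(abs(mean(fit$scores$pc1)), 1e-10)
  expect_lt(abs(mean(fit$scores$pc2)), 1e-10)
  expect_lte(sum(fit$explained_var), 1 + 1e-12)
  L <- fit$loadings
  expect_equal(crossprod(L), diag(2), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("applying the model to the training cohort reproduces the scores", {
  set.seed(6)
  expr <- make_expr(matrix(rnorm(15 * 30), nrow = 15))
  screen <- tibble::tibble(gene = expr$gene[1:10], hr = runif(10, 0.5, 2),
                           screened = TRUE)
  fit <- fit_dms(expr, screen)
  proj <- apply_dms(fit, expr)
  expect_equal(proj$dms, fit$scores$dms, tolerance = 1e-10)

  dropped <- expr[expr$gene != expr$gene[1], ]
  proj2 <- suppressMessages(apply_dms(fit, dropped))
  expect_true(all(is.finite(proj2$dms)))
  expect_equal(attr(proj2, "n_missing_genes"), 1)

  few <- expr[expr$gene %in% expr$gene[1:5], ]
  expect_error(apply_dms(fit, few), "model genes present")
})

test_that("DMS recovers the planted latent score with protective orientation", {
  co <- simulate_cohort(n_samples = 200, k_true = 2, cluster_shift = 2,
                        surv_beta = 1, seed = 7)
  labs <- as.character(co$truth_samples$true_cluster)
  called <- call_degs(moderated_t(co$expression, labs))
  screen <- suppressMessages(cox_screen(co$expression, co$clinical,
                                        candidate_genes = c(called$up, called$down)))
  fit <- fit_dms(co$expression, screen)
  r <- cor(fit$scores$dms, co$truth_samples$latent_score)
  expect_gte(abs(r), 0.8)

  # high DMS must be the longer-surviving half
  grp <- dms_groups(fit$scores, stats::median(fit$scores$dms))
  meds <- vapply(split(seq_len(200), grp$group), function(i) {
    median_survival(km_estimate(co$clinical$os_time[i], co$clinical$os_status[i]))
  }, numeric(1))
  expect_gt(meds[["High_DMS"]], meds[["Low_DMS"]])
})

test_that("a planted validation cohort separates in survival after projection", {
  train <- simulate_cohort(n_samples = 200, k_true = 2, cluster_shift = 2,
                           surv_beta = 1, seed = 8)
  valid <- simulate_cohort(n_samples = 200, k_true = 2, cluster_shift = 2,
                           surv_beta = 1, seed = 9)
  labs <- as.character(train$truth_samples$true_cluster)
  called <- call_degs(moderated_t(train$expression, labs))
  screen <- suppressMessages(cox_screen(train$expression, train$clinical,
                                        candidate_genes = c(called$up, called$down)))
  fit <- fit_dms(train$expression, screen)
  proj <- apply_dms(fit, valid$expression)
  grp <- dms_groups(proj, stats::median(proj$dms))
  lr <- logrank_test(valid$clinical$os_time, valid$clinical$os_status, grp$group)
  expect_lt(lr$p, 0.01)
})

test_that("single-gene and rank-deficient inputs fall back with a warning", {
  set.seed(10)
  expr <- make_expr(matrix(rnorm(5 * 12), nrow = 5))
  one <- tibble::tibble(gene = expr$gene[1], hr = 0.8, screened = TRUE)
  expect_warning(fit <- fit_dms(expr, one), "fewer than 2")
  expect_equal(fit$scores$pc2, rep(0, 12))
  expect_true(all(is.finite(fit$scores$dms)))
})
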