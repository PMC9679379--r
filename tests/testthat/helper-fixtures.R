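# Shared fixture builders and independent oracles. Everything is generated in
# code; no fixture files.

# expression tibble from a genes x samples matrix (names auto-filled)
make_expr <- function(m, genes = NULL, samples = NULL) {
  genes <- genes %||% rownames(m) %||% paste0("g", seq_len(nrow(m)))
  samples <- samples %||% colnames(m) %||% paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  dplyr::bind_cols(tibble::tibble(gene = genes),
                   tibble::as_tibble(as.data.frame(m)))
}

`%||%` <- rlang::`%||%`

make_clinical <- function(n, times = NULL, status = NULL, ids = NULL) {
  tibble::tibble(
    sample_id = ids %||% paste0("s", seq_len(n)),
    os_time = times %||% rep(100, n),
    os_status = status %||% rep(1, n)
  )
}

# brute-force k-medoids: global optimum over all medoid subsets
brute_force_pam <- function(D, k) {
  n <- nrow(D)
  combs <- utils::combn(n, k)
  costs <- apply(combs, 2, function(med) sum(apply(D[, med, drop = FALSE], 1, min)))
  best <- combs[, which.min(costs)]
  assign <- apply(D[, best, drop = FALSE], 1, which.min)
  list(medoids = best, clustering = assign, cost = min(costs))
}

# is a medoid set swap-optimal (no single medoid/non-medoid exchange improves)?
is_swap_optimal <- function(D, medoids, tol = 1e-12) {
  n <- nrow(D)
  cost <- function(med) sum(apply(D[, med, drop = FALSE], 1, min))
  c0 <- cost(medoids)
  for (mi in seq_along(medoids)) {
    for (h in setdiff(seq_len(n), medoids)) {
      cand <- medoids; cand[mi] <- h
      if (cost(cand) < c0 - tol) return(FALSE)
    }
  }
  TRUE
}

# independent maximally-selected cutpoint scan built on survival::survdiff
brute_force_cutpoint <- function(score, times, events, minprop = 0.1) {
  n <- length(score)
  u <- sort(unique(score))
  cands <- (head(u, -1) + tail(u, -1)) / 2
  cands <- cands[sapply(cands, function(cp) {
    min(sum(score <= cp), sum(score > cp)) / n >= minprop
  })]
  zs <- sapply(cands, function(cp) {
    g <- factor(score > cp)
    sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
    sign(sd_$obs[2] - sd_$exp[2]) * sqrt(sd_$chisq)
  })
  best <- which(abs(zs) == max(abs(zs)))[1]
  list(cutpoint = cands[best], statistic = zs[best], candidates = cands, zs = zs)
}

# exact hypergeometric upper tail from binomial coefficients (no phyper)
hyper_tail_choose <- function(k, K, N, n) {
  j <- max(k, max(0, n - (N - K))):min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
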