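# Resampling-based consensus clustering (Monti-style): repeatedly subsample
# the cohort, partition each subsample with PAM, and aggregate how often each
# pair of samples lands in the same cluster. The consensus matrix per k feeds
# the CDF / delta-area / PAC diagnostics used to choose the number of
# subtypes.

#' Consensus clustering of samples with PAM over resamples
#'
#' For each of `reps` resamples, `ceiling(p_item * n)` samples are drawn
#' without replacement and partitioned with [pam_cluster()] on the induced
#' dissimilarity (1 - Pearson correlation over the z-scored feature genes by
#' default). `consensus[i, j]` is the fraction of resamples containing both
#' `i` and `j` in which they were co-clustered. The final assignment at each
#' k cuts an average-linkage hierarchical tree of `1 - consensus` — the
#' consensus matrix itself, not any single PAM run, defines the subtypes.
#'
#' @param expr expression tibble (all genes; `features` selects the panel).
#' @param features character vector of feature genes (e.g. the regulator
#'   panel or a DEG list); default all genes.
#' @param k_range integer vector of cluster numbers to evaluate.
#' @param reps number of resamples (1000 for production runs; smaller values
#'   are fine for quick checks).
#' @param p_item fraction of samples drawn per resample.
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param seed integer seed (required: resampling must be reproducible).
#' @return object of class `consensus_result`: list with `consensus` (named
#'   list of matrices), `assignments` (tibble sample_id x k columns),
#'   `metrics` (per-k CDF area, delta-area, PAC), `cdf` (tibble of CDF
#'   curves), plus the call parameters.
#' @export
consensus_cluster <- function(expr, features = NULL, k_range = 2:5,
                              reps = 1000, p_item = 0.8,
                              distance = c("pearson", "euclidean"),
                              seed = NULL) {
  distance <- match.arg(distance)
  if (is.null(seed)) abort("consensus_cluster() requires an integer `seed`")
  if (p_item <= 0 || p_item > 1) abort("p_item must be in (0, 1]")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2)) abort("k_range values must be >= 2")

  z <- suppressWarnings(zscore_genes(
    if (is.null(features)) expr else {
      validate_expression(expr, require_unique_genes = TRUE)
      missing_f <- setdiff(features, expr$gene)
      if (length(missing_f)) abort(paste0("feature gene(s) absent: ",
                                          paste(head(missing_f, 5), collapse = ", ")))
      expr[match(features, expr$gene), , drop = FALSE]
    }))
  D <- sample_distance(z, distance = distance)
  samples <- expr_samples(z)
  n <- length(samples)
  if (max(k_range) > n) abort("largest k exceeds the number of samples")
  n_sub <- ceiling(p_item * n)

  co_sampled <- matrix(0, n, n)
  co_clustered <- setNames(lapply(k_range, function(k) matrix(0, n, n)), paste0("k", k_range))

  with_seed_if(seed, {
    for (b in seq_len(reps)) {
      idx <- sort(sample.int(n, n_sub))
      co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
      Dsub <- D[idx, idx, drop = FALSE]
      for (ki in seq_along(k_range)) {
        cl <- pam_cluster(Dsub, k_range[ki])$clustering
        same <- outer(cl, cl, "==")
        co_clustered[[ki]][idx, idx] <- co_clustered[[ki]][idx, idx] + same
      }
    }
  })

  if (any(co_sampled[upper.tri(co_sampled)] == 0)) {
    abort("some sample pairs were never co-sampled; increase `reps` (or p_item)")
  }

  consensus <- lapply(co_clustered, function(cc) {
    m <- cc / pmax(co_sampled, 1)
    diag(m) <- 1
    m <- (m + t(m)) / 2
    dimnames(m) <- list(samples, samples)
    m
  })

  assignments <- tibble(sample_id = samples)
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    hc <- hclust(as.dist(1 - consensus[[ki]]), method = "average")
    cl <- cutree(hc, k = k)
    assignments[[paste0("k", k)]] <- relabel_by_size(cl)
  }

  cdf_tbl <- purrr::map_dfr(seq_along(k_range), function(ki) {
    v <- sort(consensus[[ki]][upper.tri(consensus[[ki]])])
    tibble(k = k_range[ki], value = v, cdf = seq_along(v) / length(v))
  })

  metrics <- purrr::map_dfr(seq_along(k_range), function(ki) {
    v <- sort(consensus[[ki]][upper.tri(consensus[[ki]])])
    f <- ecdf(v)
    # area under the empirical CDF on [0, 1]
    xs <- c(0, v, 1)
    area <- sum(diff(xs) * f(xs[-length(xs)]))
    tibble(k = k_range[ki], cdf_area = area, pac = f(0.9) - f(0.1))
  })
  metrics$delta_area <- c(metrics$cdf_area[1],
                          diff(metrics$cdf_area) / head(metrics$cdf_area, -1))

  structure(list(
    consensus = consensus,
    assignments = assignments,
    metrics = metrics,
    cdf = cdf_tbl,
    k_range = k_range, reps = reps, p_item = p_item,
    distance = distance, seed = seed
  ), class = "consensus_result")
}

# deterministic cosmetic relabeling: clusters numbered 1..k by decreasing
# size, ties broken by first appearance
relabel_by_size <- function(cl) {
  sizes <- table(cl)
  ord <- order(-as.numeric(sizes), match(names(sizes), unique(as.character(cl))))
  map <- setNames(seq_along(ord), names(sizes)[ord])
  unname(map[as.character(cl)])
}

#' Recommend the number of clusters from consensus diagnostics
#'
#' Recommends the k minimizing the proportion of ambiguous clustering
#' (PAC = CDF(0.9) - CDF(0.1) of the consensus values; 0 for a perfectly
#' stable partition), ties broken toward the smaller k. The delta-area of the
#' consensus CDF — the classic elbow diagnostic — is reported alongside in
#' `metrics`; PAC is used for the recommendation because the raw CDF area
#' grows mechanically with k, which makes a fixed delta-area threshold
#' over-split even cleanly separated cohorts. When even the best PAC exceeds
#' `pac_confident` there is no clean structure at any k and the
#' recommendation is flagged low-confidence. The recommendation never
#' overrides the user: pick any k present in the result.
#'
#' @param result a `consensus_result`.
#' @param pac_confident PAC above which the call is flagged low-confidence.
#' @return list with `chosen_k`, `low_confidence`, and the `metrics` tibble.
#' @export
select_k <- function(result, pac_confident = 0.2) {
  stopifnot(inherits(result, "consensus_result"))
  m <- result$metrics
  chosen <- m$k[which.min(m$pac)]
  list(chosen_k = chosen,
       low_confidence = min(m$pac) > pac_confident,
       metrics = m)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> ", nrow(x$assignments), " samples, k in {",
      paste(x$k_range, collapse = ", "), "}, ", x$reps, " resamples (p_item = ",
      x$p_item, ", ", x$distance, " distance)\n", sep = "")
  print(x$metrics)
  invisible(x)
}
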