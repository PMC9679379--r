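# Partitioning around medoids (PAM), build + swap, written for determinism:
# greedy BUILD initialization, then first-improvement SWAP in fixed
# (medoid position, candidate index) order until no exchange lowers the total
# within-cluster dissimilarity. Identical input always yields the identical
# partition.

#' Cluster a dissimilarity matrix with PAM (k-medoids)
#'
#' @param d square symmetric non-negative dissimilarity matrix (or `dist`).
#' @param k number of clusters, `2 <= k <= n` (k = 1 allowed for degenerate use).
#' @return list with `medoids` (indices), `clustering` (1..k, cluster `i` is
#'   the cluster of medoid `medoids[i]`), `cost` (total distance of each point
#'   to its medoid).
#' @export
pam_cluster <- function(d, k) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (ncol(D) != n) abort("dissimilarity matrix must be square")
  if (k < 1 || k > n) abort(paste0("k must be in 1..n (n = ", n, ")"))
  if (any(D < -1e-12)) abort("dissimilarities must be non-negative")

  # BUILD: first medoid minimizes total distance; each next maximizes the
  # decrease in cost
  med <- unname(which.min(colSums(D)))
  d1 <- unname(D[, med])
  while (length(med) < k) {
    cand <- setdiff(seq_len(n), med)
    gains <- vapply(cand, function(j) sum(pmax(d1 - D[, j], 0)), numeric(1))
    best <- cand[which.max(gains)]
    med <- c(med, best)
    d1 <- pmin(d1, D[, best])
  }
  med <- sort(med)

  # SWAP: first strictly-improving (medoid, non-medoid) exchange, rescan
  idx <- seq_len(n)
  repeat {
    Dm <- D[, med, drop = FALSE]
    near <- max.col(-Dm, ties.method = "first")
    d1 <- Dm[cbind(idx, near)]
    if (k > 1) {
      Dm2 <- Dm
      Dm2[cbind(idx, near)] <- Inf
      d2 <- Dm2[cbind(idx, max.col(-Dm2, ties.method = "first"))]
    } else {
      d2 <- rep(Inf, n)
    }
    total <- sum(d1)
    improved <- FALSE
    for (mi in seq_along(med)) {
      own <- near == mi
      for (h in setdiff(idx, med)) {
        dh <- D[, h]
        newd <- pmin(d1, dh)
        newd[own] <- pmin(d2[own], dh[own])
        if (sum(newd) < total - 1e-12) {
          med[mi] <- h
          med <- sort(med)
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }

  Dm <- D[, med, drop = FALSE]
  clustering <- max.col(-Dm, ties.method = "first")
  list(medoids = med, clustering = clustering,
       cost = sum(Dm[cbind(idx, clustering)]))
}

# correlation distance between samples over a feature set; expr must already
# be restricted to the features and z-scored when z = TRUE upstream
sample_distance <- function(expr, features = NULL,
                            distance = c("pearson", "euclidean")) {
  distance <- match.arg(distance)
  m <- expr_as_matrix(expr)
  if (!is.null(features)) {
    missing_f <- setdiff(features, rownames(m))
    if (length(missing_f)) {
      abort(paste0("feature gene(s) absent from expression: ",
                   paste(head(missing_f, 5), collapse = ", ")))
    }
    m <- m[features, , drop = FALSE]
  }
  if (distance == "pearson") {
    if (nrow(m) < 2) abort("correlation distance needs >= 2 features")
    d <- 1 - cor(m)
  } else {
    d <- as.matrix(stats::dist(t(m)))
  }
  d[d < 0] <- 0
  diag(d) <- 0
  d
}
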