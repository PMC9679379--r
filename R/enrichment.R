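# Enrichment analyses: weighted Kolmogorov-Smirnov GSEA with a gene-set
# permutation null, hypergeometric over-representation, and per-sample
# signature scores (mean-z or ssGSEA-style rank integral).

#' GSEA enrichment score for one gene set
#'
#' Walks the ranked list: positions in the set advance the running sum by
#' `|stat|^weight_p` (normalized over the set), positions outside retreat by
#' `1/(N - K)`. The enrichment score is the extremum of the running sum by
#' absolute value; the leading edge is the set members at or before (after,
#' for negative ES) the extremum.
#'
#' @param stats named numeric vector of ranking statistics (e.g. log2 fold
#'   changes), any order; sorted decreasingly internally.
#' @param gene_set character vector of member genes; must intersect the list.
#' @param weight_p weighting exponent (0 = classic KS, 1 = standard GSEA).
#' @return list: `es`, `running_sum` (tibble `rank`, `gene`, `running`),
#'   `leading_edge`.
#' @export
gsea_es <- function(stats, gene_set, weight_p = 1) {
  if (is.null(names(stats))) abort("stats must be named by gene")
  stats <- sort(stats, decreasing = TRUE)
  hit <- names(stats) %in% gene_set
  if (!any(hit)) abort("gene set has no member in the ranked list")
  if (all(hit)) {
    rs <- cumsum(rep(1 / length(stats), length(stats)))
  } else {
    w <- abs(stats)^weight_p
    wh <- ifelse(hit, w, 0)
    denom <- sum(wh)
    if (denom == 0) { # all in-set stats are exactly 0: fall back to equal steps
      wh <- as.numeric(hit); denom <- sum(wh)
    }
    rs <- cumsum(wh / denom - (!hit) / (length(stats) - sum(hit)))
  }
  i_max <- which.max(abs(rs))
  es <- rs[i_max]
  le <- if (es >= 0) names(stats)[seq_len(i_max)][hit[seq_len(i_max)]]
        else names(stats)[i_max:length(stats)][hit[i_max:length(stats)]]
  list(es = es,
       running_sum = tibble(rank = seq_along(stats), gene = names(stats), running = rs),
       leading_edge = le)
}

#' GSEA over a gene-set collection with a permutation null
#'
#' Computes the enrichment score of every set against the ranked list, then a
#' null of `n_perm` random same-size gene sets per set size. The normalized
#' enrichment score divides ES by the mean |null ES| of the same sign; the
#' empirical p compares |ES| to the same-sign null, and BH adjustment is
#' applied across sets.
#'
#' @param stats named ranking statistics.
#' @param gene_sets tibble from [read_gmt()] (columns `set`, `genes`) or a
#'   named list of gene vectors.
#' @param n_perm permutations per set size.
#' @param weight_p weighting exponent.
#' @param seed integer seed (required).
#' @param min_size,max_size set-size filter after intersecting with the list.
#' @return tibble per set: `set`, `size`, `es`, `nes`, `p`, `fdr`,
#'   `leading_edge` (list-column).
#' @export
gsea_run <- function(stats, gene_sets, n_perm = 1000, weight_p = 1,
                     seed = NULL, min_size = 2, max_size = 500) {
  if (is.null(seed)) abort("gsea_run() requires an integer `seed`")
  gs <- as_gene_set_list(gene_sets)
  stats <- sort(stats, decreasing = TRUE)
  genes <- names(stats)
  gs <- lapply(gs, intersect, y = genes)
  sizes <- lengths(gs)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) abort("no gene set passes the size filter after intersection")
  gs <- gs[keep]
  sizes <- sizes[keep]

  obs <- purrr::map(gs, function(g) gsea_es(stats, g, weight_p))
  es <- vapply(obs, `[[`, numeric(1), "es")

  null_by_size <- with_seed_if(seed, {
    lapply(setNames(nm = sort(unique(sizes))), function(sz) {
      vapply(seq_len(n_perm), function(b) {
        gsea_es(stats, sample(genes, sz), weight_p)$es
      }, numeric(1))
    })
  })

  res <- purrr::imap_dfr(gs, function(g, nm) {
    e <- es[[nm]]
    null <- null_by_size[[as.character(length(g))]]
    same <- if (e >= 0) null[null >= 0] else null[null < 0]
    nes <- if (length(same) && mean(abs(same)) > 0) e / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(e))) / (1 + length(same))
    tibble(set = nm, size = length(g), es = e, nes = nes, p = p,
           leading_edge = list(obs[[nm]]$leading_edge))
  })
  res$fdr <- p.adjust(res$p, method = "BH")
  res[, c("set", "size", "es", "nes", "p", "fdr", "leading_edge")]
}

as_gene_set_list <- function(gene_sets) {
  if (is.data.frame(gene_sets)) {
    if (!all(c("set", "genes") %in% names(gene_sets))) {
      abort("gene_sets tibble needs `set` and `genes` columns (see read_gmt())")
    }
    gs <- setNames(gene_sets$genes, gene_sets$set)
  } else if (is.list(gene_sets)) {
    gs <- gene_sets
    if (is.null(names(gs))) abort("gene_sets list must be named")
  } else abort("gene_sets must be a tibble or a named list")
  if (any(!lengths(gs))) abort("empty gene set(s) present")
  lapply(gs, unique)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing `k` list
#' genes in a set of size `K` drawn from a universe of size `N`, for each
#' set; BH adjustment across sets.
#'
#' @param gene_list character vector (e.g. up-regulated DEGs).
#' @param gene_sets tibble from [read_gmt()] or named list.
#' @param universe character vector of all testable genes.
#' @param min_size,max_size set-size filter (after intersecting with the
#'   universe).
#' @return tibble per set: `set`, `overlap`, `set_size`, `list_size`,
#'   `universe_size`, `p`, `q`, `hits` (list-column).
#' @export
ora_hypergeometric <- function(gene_list, gene_sets, universe,
                               min_size = 1, max_size = Inf) {
  universe <- unique(universe)
  gene_list <- unique(intersect(gene_list, universe))
  if (!length(gene_list)) abort("gene_list has no gene in the universe")
  gs <- lapply(as_gene_set_list(gene_sets), intersect, y = universe)
  sizes <- lengths(gs)
  gs <- gs[sizes >= min_size & sizes <= max_size]
  if (!length(gs)) abort("no gene set passes the size filter")
  res <- purrr::imap_dfr(gs, function(g, nm) {
    k <- length(intersect(gene_list, g))
    tibble(set = nm, overlap = k, set_size = length(g),
           list_size = length(gene_list), universe_size = length(universe),
           p = phyper(k - 1, length(g), length(universe) - length(g),
                      length(gene_list), lower.tail = FALSE),
           hits = list(intersect(gene_list, g)))
  })
  res$q <- p.adjust(res$p, method = "BH")
  res[, c("set", "overlap", "set_size", "list_size", "universe_size", "p", "q", "hits")]
}

#' Per-sample signature scores
#'
#' `mean_z`: mean of the z-scored member genes per sample — the simple,
#' interpretable stand-in for deconvolution when only relative enrichment is
#' needed. `ssgsea`: single-sample rank-based enrichment (difference of
#' weighted in-set and uniform out-of-set empirical CDFs, integrated over the
#' ranking, exponent `alpha`).
#'
#' @param expr expression tibble.
#' @param gene_sets tibble from [read_gmt()] or named list.
#' @param method `"mean_z"` or `"ssgsea"`.
#' @param alpha rank-weight exponent for ssgsea.
#' @return tibble: `sample_id` plus one numeric column per gene set.
#' @export
signature_score <- function(expr, gene_sets, method = c("mean_z", "ssgsea"),
                            alpha = 0.25) {
  method <- match.arg(method)
  gs <- as_gene_set_list(gene_sets)
  m <- expr_as_matrix(expr)
  gs <- lapply(gs, intersect, y = rownames(m))
  if (any(!lengths(gs))) {
    abort(paste0("gene set(s) with no gene in the expression table: ",
                 paste(names(gs)[!lengths(gs)], collapse = ", ")))
  }
  out <- tibble(sample_id = colnames(m))
  if (method == "mean_z") {
    mu <- rowMeans(m); s <- row_sd_pop(m)
    s[s == 0] <- 1                       # constant genes contribute z = 0
    z <- (m - mu) / s
    for (nm in names(gs)) out[[nm]] <- unname(colMeans(z[gs[[nm]], , drop = FALSE]))
  } else {
    n_genes <- nrow(m)
    for (nm in names(gs)) out[[nm]] <- NA_real_
    for (j in seq_len(ncol(m))) {
      r <- rank(m[, j], ties.method = "average")       # high expression = high rank
      ord <- order(r, decreasing = TRUE)
      rr <- r[ord]^alpha
      gene_ord <- rownames(m)[ord]
      for (nm in names(gs)) {
        hit <- gene_ord %in% gs[[nm]]
        p_hit <- cumsum(ifelse(hit, rr, 0)) / sum(rr[hit])
        p_miss <- cumsum(!hit) / (n_genes - sum(hit))
        out[[nm]][j] <- sum(p_hit - p_miss)
      }
    }
  }
  out
}
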