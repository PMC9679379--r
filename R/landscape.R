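# Descriptive genomics of the regulator panel: mutation / CNV frequencies,
# tumor-vs-normal style two-group tests, correlation matrices and grouping
# crosstabs.

#' Per-gene mutation frequency over a sample universe
#'
#' Percentage of profiled samples carrying at least one mutation in each panel
#' gene. The denominator is `sample_universe` (all profiled samples), not just
#' the mutated ones, and a sample counts once per gene no matter how many of
#' its variants hit that gene.
#'
#' @param mutations mutation tibble (`sample_id`, `gene`, `variant_class`).
#' @param sample_universe character vector of all profiled sample ids.
#' @param panel tibble with a `gene` column (default regulator panel).
#' @return tibble `gene`, `n_mutated`, `pct_mutated`.
#' @export
mutation_frequency <- function(mutations, sample_universe,
                               panel = default_regulator_panel()) {
  if (!length(sample_universe)) abort("sample_universe is empty")
  sample_universe <- unique(sample_universe)
  hits <- mutations |>
    dplyr::filter(.data$gene %in% panel$gene, .data$sample_id %in% sample_universe) |>
    dplyr::distinct(.data$gene, .data$sample_id) |>
    dplyr::count(.data$gene, name = "n_mutated")
  panel |>
    dplyr::select("gene") |>
    dplyr::left_join(hits, by = "gene") |>
    dplyr::mutate(n_mutated = dplyr::coalesce(.data$n_mutated, 0L),
                  pct_mutated = 100 * .data$n_mutated / length(sample_universe))
}

#' Per-gene CNV gain and loss frequency
#'
#' @param cnv CNV call tibble (genes x samples, calls in -2..2).
#' @param panel tibble with a `gene` column; rows restricted to it.
#' @param gain_threshold call at or above which a sample counts as gained.
#' @param loss_threshold call at or below which a sample counts as lost.
#' @return tibble `gene`, `pct_gain`, `pct_loss`.
#' @export
cnv_frequency <- function(cnv, panel = default_regulator_panel(),
                          gain_threshold = 1, loss_threshold = -1) {
  m <- expr_as_matrix(cnv)
  m <- m[rownames(m) %in% panel$gene, , drop = FALSE]
  if (!nrow(m)) abort("no panel genes present in the CNV table")
  tibble(
    gene = rownames(m),
    pct_gain = unname(100 * rowMeans(m >= gain_threshold)),
    pct_loss = unname(100 * rowMeans(m <= loss_threshold))
  )
}

#' Two-group per-gene expression test
#'
#' Wilcoxon rank-sum (default) or Welch t test of every gene between two
#' sample groups, e.g. tumor vs normal. The Wilcoxon p-value is exact when the
#' smaller group has at most 10 samples and there are no ties, otherwise the
#' normal approximation with tie and continuity correction is used.
#'
#' @param expr expression tibble.
#' @param group_labels vector (or factor) of length `n_samples` with exactly
#'   two levels; `levels(factor(group_labels))[1]` is group A.
#' @param method `"wilcoxon"` or `"t"`.
#' @return tibble per gene: `statistic`, `p`, `p_adj` (BH), `direction`
#'   (`up_in_A` / `up_in_B` by difference of group medians, A first level).
#' @export
two_group_expression_test <- function(expr, group_labels,
                                      method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  m <- expr_as_matrix(expr)
  g <- factor(group_labels)
  if (length(g) != ncol(m)) abort("group_labels length must equal the number of samples")
  if (nlevels(g) != 2) abort("exactly two groups are required")
  a <- g == levels(g)[1]
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    xa <- m[i, a]; xb <- m[i, !a]
    if (method == "wilcoxon") {
      exact <- min(length(xa), length(xb)) <= 10 && !anyDuplicated(c(xa, xb))
      ht <- suppressWarnings(wilcox.test(xa, xb, exact = exact, correct = TRUE))
    } else {
      ht <- stats::t.test(xa, xb)
    }
    delta <- median(xa) - median(xb)
    tibble(gene = rownames(m)[i],
           statistic = unname(ht$statistic),
           p = ht$p.value,
           direction = ifelse(delta >= 0, "up_in_A", "up_in_B"))
  })
  res$p_adj <- p.adjust(res$p, method = "BH")
  res[, c("gene", "statistic", "p", "p_adj", "direction")]
}

#' Gene-gene (or gene-feature) correlation matrix with p-values
#'
#' Spearman (default) or Pearson correlations between the rows named in
#' `features` across samples, with p-values from the t approximation
#' `t = r * sqrt((n-2)/(1-r^2))`.
#'
#' @param expr expression tibble (or any feature-by-sample tibble, e.g.
#'   signature scores transposed).
#' @param features character vector of row names to correlate; default all.
#' @param method `"spearman"` or `"pearson"`.
#' @return list with symmetric unit-diagonal matrices `r` and `p`.
#' @export
correlation_matrix <- function(expr, features = NULL,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  m <- expr_as_matrix(expr)
  if (!is.null(features)) {
    missing_f <- setdiff(features, rownames(m))
    if (length(missing_f)) abort(paste0("features absent from table: ",
                                        paste(head(missing_f, 5), collapse = ", ")))
    m <- m[features, , drop = FALSE]
  }
  n <- ncol(m)
  if (n < 3) abort("need at least 3 samples for correlation")
  r <- cor(t(m), method = method)
  r[r > 1] <- 1; r[r < -1] <- -1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  list(r = r, p = p)
}

#' Cross-tabulate sample groupings
#'
#' Counts samples per combination of one or more labelings (e.g. 5mC subtype
#' x DEG gene cluster x DMS group) — the tabular stand-in for an alluvial
#' transition diagram.
#'
#' @param ... named vectors/factors of equal length.
#' @return tibble with one column per grouping plus `n`.
#' @export
group_crosstab <- function(...) {
  labs <- list(...)
  if (!length(labs)) abort("supply at least one grouping vector")
  if (is.null(names(labs)) || any(!nzchar(names(labs)))) {
    names(labs) <- paste0("group", seq_along(labs))
  }
  len <- unique(lengths(labs))
  if (length(len) != 1) abort("all grouping vectors must have the same length")
  as_tibble(labs) |>
    dplyr::count(dplyr::across(dplyr::everything()), name = "n") |>
    dplyr::arrange(dplyr::across(-dplyr::all_of("n")))
}

#' K-group per-gene test (Kruskal-Wallis or one-way ANOVA)
#'
#' Compares each gene across three or more groups, the nonparametric /
#' parametric pair used for subtype factor comparisons.
#'
#' @param expr expression tibble.
#' @param group_labels vector of length `n_samples`, >= 2 levels.
#' @param method `"kruskal"` or `"anova"`.
#' @return tibble per gene: `statistic`, `df`, `p`, `p_adj` (BH).
#' @export
kgroup_test <- function(expr, group_labels, method = c("kruskal", "anova")) {
  method <- match.arg(method)
  m <- expr_as_matrix(expr)
  g <- factor(group_labels)
  if (length(g) != ncol(m)) abort("group_labels length must equal the number of samples")
  if (nlevels(g) < 2) abort("need at least two groups")
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    x <- m[i, ]
    if (method == "kruskal") {
      ht <- kruskal.test(x, g)
      tibble(gene = rownames(m)[i], statistic = unname(ht$statistic),
             df = unname(ht$parameter), p = ht$p.value)
    } else {
      av <- anova(aov(x ~ g))
      tibble(gene = rownames(m)[i], statistic = av$`F value`[1],
             df = av$Df[1], p = av$`Pr(>F)`[1])
    }
  })
  res$p_adj <- p.adjust(res$p, method = "BH")
  res
}
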