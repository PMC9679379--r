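# Cohort cleaning: the four clinical/expression filters applied before any
# analysis, duplicate-row collapse, sample alignment and per-gene z-scoring.

#' Filter clinical samples by follow-up quality
#'
#' Applies the standard cohort-cleaning rules: drop samples with no follow-up
#' at all (both time and status missing), unknown survival time, survival
#' time shorter than `min_days` (strictly; a sample at exactly `min_days` is
#' kept), or unknown survival status. The rules are predicates on each sample,
#' so the retained set does not depend on the order they are applied in.
#'
#' @param clinical a clinical tibble (see [read_clinical()]).
#' @param min_days minimum follow-up in days; default 30.
#' @return the filtered tibble, with an `exclusions` attribute: a tibble of
#'   per-rule counts (a sample missing both fields counts only under
#'   `no_followup`).
#' @export
filter_clinical_samples <- function(clinical, min_days = 30) {
  validate_clinical(clinical)
  no_fu <- is.na(clinical$os_time) & is.na(clinical$os_status)
  no_time <- is.na(clinical$os_time) & !no_fu
  short <- !is.na(clinical$os_time) & clinical$os_time < min_days
  no_status <- is.na(clinical$os_status) & !no_fu
  keep <- !(no_fu | no_time | short | no_status)
  if (!any(keep)) abort("no samples survive the clinical filters")
  out <- clinical[keep, , drop = FALSE]
  attr(out, "exclusions") <- tibble(
    rule = c("no_followup", "unknown_time", paste0("time_lt_", min_days), "unknown_status"),
    n_excluded = c(sum(no_fu), sum(no_time), sum(short), sum(no_status))
  )
  out
}

#' Collapse duplicate gene rows to per-sample medians
#'
#' Rows whose identifier maps to multiple genes (contains one of
#' `multi_separators`) are removed first; remaining duplicate symbols are
#' collapsed to the per-sample median across their rows.
#'
#' @param expr expression tibble.
#' @param multi_separators substrings marking multi-gene probe identifiers.
#' @return expression tibble with unique gene symbols; attributes
#'   `n_multi_gene_rows` and `n_collapsed_symbols` record what was done.
#' @export
collapse_duplicate_genes <- function(expr, multi_separators = c("///", ";")) {
  validate_expression(expr)
  genes <- trimws(expr$gene)
  multi <- rep(FALSE, length(genes))
  for (sep in multi_separators) multi <- multi | grepl(sep, genes, fixed = TRUE)
  kept <- expr[!multi, , drop = FALSE]
  kept$gene <- genes[!multi]
  ndup_sym <- length(unique(kept$gene[duplicated(kept$gene)]))
  if (ndup_sym > 0) {
    kept <- kept |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(dplyr::across(dplyr::everything(), median), .groups = "drop") |>
      # preserve first-appearance gene order
      dplyr::arrange(match(.data$gene, genes[!multi]))
  }
  attr(kept, "n_multi_gene_rows") <- sum(multi)
  attr(kept, "n_collapsed_symbols") <- ndup_sym
  kept
}

#' Align an expression matrix and a clinical table to their common samples
#'
#' Intersects the sample sets, orders both sides identically (lexicographic
#' sample id, so the result is independent of input order) and records how
#' many samples each side lost.
#'
#' @param expr expression tibble.
#' @param clinical clinical tibble.
#' @return a list of class `cohort_bundle` with `expression`, `clinical` and
#'   `exclusion_log`.
#' @export
align_cohort <- function(expr, clinical) {
  validate_expression(expr, require_unique_genes = TRUE)
  validate_clinical(clinical)
  common <- sort(intersect(expr_samples(expr), clinical$sample_id))
  if (!length(common)) abort("expression and clinical tables share no samples")
  out_expr <- expr[, c("gene", common), drop = FALSE]
  out_clin <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  structure(list(
    expression = out_expr,
    clinical = out_clin,
    exclusion_log = tibble(
      side = c("expression", "clinical"),
      n_in = c(length(expr_samples(expr)), nrow(clinical)),
      n_dropped = c(length(expr_samples(expr)), nrow(clinical)) - length(common)
    )
  ), class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle> ", length(expr_samples(x$expression)), " aligned samples, ",
      nrow(x$expression), " genes\n", sep = "")
  print(x$exclusion_log)
  invisible(x)
}

#' Z-score each gene across samples
#'
#' Centers and scales every gene to mean 0, SD 1 using the population SD
#' (divisor n). Genes with zero variance carry no between-sample information
#' and are dropped with a warning.
#'
#' @param expr expression tibble.
#' @param ddof 0 (population SD, default) or 1 (sample SD).
#' @return z-scored expression tibble.
#' @export
zscore_genes <- function(expr, ddof = 0) {
  m <- expr_as_matrix(expr)
  n <- ncol(m)
  if (!ddof %in% c(0, 1)) abort("ddof must be 0 or 1")
  if (n - ddof < 1) abort("too few samples to z-score")
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (n - ddof))
  zero <- s == 0 | !is.finite(s)
  if (any(zero)) {
    warn(paste0(sum(zero), " zero-variance gene(s) dropped: ",
                paste(head(rownames(m)[zero], 5), collapse = ", "),
                if (sum(zero) > 5) ", ..." else ""))
    m <- m[!zero, , drop = FALSE]; mu <- mu[!zero]; s <- s[!zero]
  }
  if (!nrow(m)) abort("no genes left after dropping zero-variance genes")
  matrix_as_expr((m - mu) / s)
}
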