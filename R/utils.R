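# Internal helpers shared across modules.
#
# The package-wide convention for an expression table is a tibble whose first
# column (`gene`) holds unique gene symbols and whose remaining columns are one
# numeric column per sample, on the log2 scale.

# expression tibble -> genes x samples numeric matrix
expr_as_matrix <- function(expr) {
  validate_expression(expr)
  m <- as.matrix(expr[, -1, drop = FALSE])
  mode(m) <- "double"
  rownames(m) <- expr$gene
  m
}

# genes x samples matrix -> expression tibble
matrix_as_expr <- function(m) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(gene = rownames(m)), out)
}

validate_expression <- function(expr, require_unique_genes = FALSE) {
  if (!is.data.frame(expr) || ncol(expr) < 2) {
    abort("expression table must be a data frame with a `gene` column plus one column per sample")
  }
  if (names(expr)[1] != "gene") {
    abort("first column of an expression table must be named `gene`")
  }
  samples <- names(expr)[-1]
  if (anyDuplicated(samples)) {
    abort(paste0("duplicated sample ids: ", paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  num_ok <- vapply(expr[-1], is.numeric, logical(1))
  if (!all(num_ok)) {
    abort(paste0("non-numeric sample columns: ", paste(samples[!num_ok], collapse = ", ")))
  }
  if (require_unique_genes && anyDuplicated(expr$gene)) {
    abort("duplicate gene symbols present; collapse_duplicate_genes() first")
  }
  invisible(expr)
}

validate_clinical <- function(clinical) {
  required <- c("sample_id", "os_time", "os_status")
  missing_cols <- setdiff(required, names(clinical))
  if (length(missing_cols)) {
    abort(paste0("clinical table is missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(clinical$sample_id)) {
    abort("clinical sample_id values must be unique")
  }
  st <- clinical$os_status
  if (!all(is.na(st) | st %in% c(0, 1))) {
    abort("os_status must be 0 (censored), 1 (event) or missing")
  }
  if (any(!is.na(clinical$os_time) & clinical$os_time < 0)) {
    abort("os_time must be non-negative")
  }
  invisible(clinical)
}

expr_samples <- function(expr) names(expr)[-1]

# population (ddof = 0) standard deviation by row
row_sd_pop <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowMeans((m - mu)^2))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples,
#' invariant to label permutation. Used throughout to compare discovered
#' clusters with planted ground truth.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a single number, 1 for identical partitions, ~0 for independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# run `code` under a temporary RNG state seeded with `seed`; NULL seed = use
# the current stream (still reproducible if the caller seeded it)
with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}
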