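# Readers and writers for the plain-text formats the pipeline exchanges:
# expression TSV (genes x samples), clinical TSV, GMT gene sets, MAF-lite
# mutation calls and GISTIC-style 5-level CNV calls. Loaders validate rather
# than repair: nothing is silently dropped, every anomaly is flagged or fatal.

read_delim_chr <- function(path, delim) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (file.size(path) == 0) abort(paste0("empty file: ", path))
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    na = c("", "NA"), show_col_types = FALSE, progress = FALSE,
                    name_repair = "minimal")
}

#' Read a gene-by-sample expression table
#'
#' Expects a delimited text file with gene identifiers in the first column and
#' one column per sample. Values are kept as-is (assumed log2 scale) unless
#' `log2_offset` is given, in which case `log2(x + log2_offset)` is applied —
#' the usual transform for raw TCGA-style abundance values.
#'
#' Duplicate gene rows are *not* collapsed here (see
#' [collapse_duplicate_genes()]); their count is reported in the
#' `n_duplicate_genes` attribute and a message. Duplicate sample ids are an
#' error. Missing cells are refused unless `impute_median = TRUE`, which fills
#' them with the per-gene median.
#'
#' @param path file path.
#' @param delim field delimiter, default tab.
#' @param log2_offset if non-`NULL`, apply `log2(x + log2_offset)`.
#' @param impute_median fill missing cells with the per-gene median.
#' @return a tibble with a `gene` column plus one numeric column per sample.
#' @export
read_expression <- function(path, delim = "\t", log2_offset = NULL, impute_median = FALSE) {
  raw <- read_delim_chr(path, delim)
  if (ncol(raw) < 2) abort("expression file needs a gene column plus at least one sample column")
  samples <- names(raw)[-1]
  if (anyDuplicated(samples)) {
    abort(paste0("duplicated sample id in header: ",
                 paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  genes <- trimws(raw[[1]])
  vals <- lapply(seq_along(samples), function(j) {
    x <- raw[[j + 1]]
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      abort(paste0("non-numeric expression value '", x[bad[1]], "' at gene '",
                   genes[bad[1]], "', sample '", samples[j], "'"))
    }
    out
  })
  m <- do.call(cbind, vals)
  colnames(m) <- samples
  if (anyNA(m)) {
    if (!impute_median) {
      abort(paste0(sum(is.na(m)), " missing expression value(s); set impute_median = TRUE to fill with per-gene medians"))
    }
    for (i in which(rowSums(is.na(m)) > 0)) {
      m[i, is.na(m[i, ])] <- median(m[i, ], na.rm = TRUE)
    }
  }
  if (!is.null(log2_offset)) m <- log2(m + log2_offset)
  rownames(m) <- genes
  expr <- matrix_as_expr(m)
  ndup <- sum(duplicated(genes))
  if (ndup > 0) {
    inform(paste0(ndup, " duplicated gene symbol row(s); collapse_duplicate_genes() will take per-sample medians"))
  }
  attr(expr, "n_duplicate_genes") <- ndup
  expr
}

#' Read a clinical table with overall-survival follow-up
#'
#' Requires columns `sample_id`, `os_time` (days) and `os_status` (1 = death,
#' 0 = censored). Unknown survival is kept as `NA` — exclusion is the job of
#' [filter_clinical_samples()], so loading never changes the cohort. Any other
#' columns are carried along as covariates (numeric where possible).
#'
#' @param path file path.
#' @param delim field delimiter, default tab.
#' @return a tibble, one row per sample.
#' @export
read_clinical <- function(path, delim = "\t") {
  raw <- read_delim_chr(path, delim)
  required <- c("sample_id", "os_time", "os_status")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("clinical file is missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- raw
  out$sample_id <- trimws(out$sample_id)
  out$os_time <- suppressWarnings(as.numeric(raw$os_time))
  bad_time <- which(!is.na(raw$os_time) & is.na(out$os_time))
  if (length(bad_time)) abort(paste0("non-numeric os_time '", raw$os_time[bad_time[1]], "' for sample ", out$sample_id[bad_time[1]]))
  out$os_status <- suppressWarnings(as.numeric(raw$os_status))
  for (col in setdiff(names(out), required)) {
    num <- suppressWarnings(as.numeric(out[[col]]))
    if (!any(!is.na(out[[col]]) & is.na(num))) out[[col]] <- num
  }
  validate_clinical(out)
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name<tab>description<tab>gene1<tab>gene2...`.
#' Duplicate genes within a set are removed (first occurrence kept); a line
#' with fewer than three fields is an error naming the line.
#'
#' @param path file path.
#' @return a tibble with columns `set`, `description` and a list-column
#'   `genes`; one row per set.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(paste0("empty GMT file: ", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- purrr::imap(parts, function(p, i) {
    p <- trimws(p)
    genes <- unique(p[-(1:2)][nzchar(p[-(1:2)])])
    if (length(p) < 3 || !length(genes)) {
      abort(paste0("GMT line ", i, " has no member genes (need name, description, >=1 gene)"))
    }
    tibble(set = p[1], description = p[2], genes = list(genes))
  })
  out <- dplyr::bind_rows(sets)
  if (anyDuplicated(out$set)) {
    abort(paste0("duplicate gene-set names: ", paste(unique(out$set[duplicated(out$set)]), collapse = ", ")))
  }
  out
}

#' Read MAF-lite mutation calls
#'
#' Minimal mutation table: columns `sample_id`, `gene`, `variant_class`.
#' Exact duplicate rows are removed (deduplication count reported via message).
#'
#' @param path file path.
#' @param delim field delimiter, default tab.
#' @return tibble of mutation calls.
#' @export
read_maf <- function(path, delim = "\t") {
  raw <- read_delim_chr(path, delim)
  required <- c("sample_id", "gene", "variant_class")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("mutation file is missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- dplyr::mutate(raw, dplyr::across(dplyr::all_of(required), trimws))
  ndup <- sum(duplicated(out[required]))
  out <- dplyr::distinct(out, dplyr::across(dplyr::all_of(required)))
  if (ndup > 0) inform(paste0(ndup, " duplicate mutation record(s) removed"))
  out
}

#' Read GISTIC-style per-gene CNV calls
#'
#' Genes in the first column, samples in the header, integer calls in
#' \{-2, -1, 0, 1, 2\} (deep loss .. high-level gain). Any other value is an
#' error.
#'
#' @param path file path.
#' @param delim field delimiter, default tab.
#' @return a tibble shaped like an expression table but with integer calls.
#' @export
read_cnv <- function(path, delim = "\t") {
  cnv <- read_expression(path, delim = delim)
  m <- expr_as_matrix(cnv)
  bad <- which(!(m %in% c(-2, -1, 0, 1, 2)))
  if (length(bad)) {
    abort(paste0("CNV call out of the 5-level code {-2..2}: value ", m[bad[1]],
                 " at gene '", rownames(m)[(bad[1] - 1) %% nrow(m) + 1], "'"))
  }
  cnv
}

#' Write a result table deterministically
#'
#' Tab-separated output with numeric columns formatted at a fixed number of
#' significant digits so that re-runs of the same analysis are byte-identical.
#' List-columns (e.g. gene-set members) are collapsed with commas.
#'
#' @param x a data frame.
#' @param path output path.
#' @param digits significant digits for numeric columns.
#' @return `x`, invisibly (pipe-friendly).
#' @export
write_result_tsv <- function(x, path, digits = 7) {
  out <- as_tibble(x)
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.list),
                                          ~ purrr::map_chr(.x, paste, collapse = ",")))
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.double),
                                          ~ ifelse(is.na(.x), NA_character_,
                                                   formatC(.x, digits = digits, format = "g"))))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(x)
}
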