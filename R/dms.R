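# The DNA methylation score (DMS): univariate Cox screening of candidate
# genes, per-gene z-scoring, PCA, and per-sample DMS = s1*PC1 + s2*PC2 with a
# data-anchored orientation so that a high DMS tracks protective expression.

#' Univariate Cox screening of candidate genes
#'
#' Fits a proportional-hazards model `Surv(os_time, os_status) ~ gene` for
#' each candidate gene (Breslow tie handling) and keeps genes whose Wald p is
#' below `alpha`, irrespective of hazard direction. Genes with no expression
#' variance or a non-converging fit are flagged and excluded, never silently
#' dropped.
#'
#' @param expr expression tibble.
#' @param clinical clinical tibble covering the expression samples.
#' @param candidate_genes genes to screen (default: all rows of `expr`).
#' @param alpha Wald p-value threshold for retention.
#' @return tibble per candidate: `coef`, `hr`, `se`, `p`, `screened`,
#'   `status` (`ok`, `constant`, `failed`).
#' @export
cox_screen <- function(expr, clinical, candidate_genes = NULL, alpha = 0.05) {
  validate_clinical(clinical)
  m <- expr_as_matrix(expr)
  candidate_genes <- candidate_genes %||% rownames(m)
  missing_g <- setdiff(candidate_genes, rownames(m))
  if (length(missing_g)) abort(paste0("candidate gene(s) absent from expression: ",
                                      paste(head(missing_g, 5), collapse = ", ")))
  idx <- match(expr_samples(expr), clinical$sample_id)
  if (anyNA(idx)) abort("clinical table does not cover every expression sample")
  cl <- clinical[idx, , drop = FALSE]
  if (anyNA(cl$os_time) || anyNA(cl$os_status)) {
    abort("survival fields contain missing values; run filter_clinical_samples() first")
  }
  if (sum(cl$os_status) < 1) abort("no events in the cohort; Cox screening impossible")
  surv <- survival::Surv(cl$os_time, cl$os_status)

  res <- purrr::map_dfr(candidate_genes, function(g) {
    x <- m[g, ]
    if (sd(x) == 0) {
      return(tibble(gene = g, coef = NA_real_, hr = NA_real_, se = NA_real_,
                    p = NA_real_, status = "constant"))
    }
    fit <- tryCatch(
      suppressWarnings(survival::coxph(surv ~ x, ties = "breslow")),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(stats::coef(fit)[1])) {
      return(tibble(gene = g, coef = NA_real_, hr = NA_real_, se = NA_real_,
                    p = NA_real_, status = "failed"))
    }
    sm <- summary(fit)
    tibble(gene = g, coef = unname(stats::coef(fit)[1]),
           hr = unname(exp(stats::coef(fit)[1])),
           se = unname(sqrt(fit$var[1, 1])),
           p = unname(sm$coefficients[1, "Pr(>|z|)"]),
           status = "ok")
  })
  res$screened <- !is.na(res$p) & res$p < alpha
  n_bad <- sum(res$status != "ok")
  if (n_bad) inform(paste0(n_bad, " gene(s) excluded from screening (constant or failed fit)"))
  res
}

#' Fit the DMS model on a training cohort
#'
#' Z-scores the screened genes, runs PCA (SVD of the samples x genes
#' standardized matrix), and scores each sample as
#' `DMS = s1 * PC1 + s2 * PC2`. The orientation signs `s1, s2` are chosen so
#' that each oriented component correlates non-negatively with the mean
#' z-expression of the protective genes (those screened with hazard ratio
#' < 1); this pins the otherwise arbitrary PCA signs so that a *high* DMS
#' means protective expression, i.e. better expected prognosis.
#'
#' @param expr expression tibble (training cohort).
#' @param screen output of [cox_screen()] (or a character vector of genes, in
#'   which case all are treated as screened and the anchor uses genes with
#'   negative PC1 loading correlation — supply the screen table for the full
#'   orientation rule).
#' @return list of class `dms_model` with elements `genes`, `center`,
#'   `scale`, `loadings` (genes x 2), `explained_var`, `signs`, and `scores`
#'   (a tibble: `sample_id`, `pc1`, `pc2`, `dms`).
#' @export
fit_dms <- function(expr, screen) {
  if (is.character(screen)) {
    screen <- tibble(gene = screen, hr = NA_real_, screened = TRUE)
  }
  genes <- screen$gene[screen$screened]
  if (!length(genes)) abort("no screened genes; nothing to score")
  m <- expr_as_matrix(expr)
  missing_g <- setdiff(genes, rownames(m))
  if (length(missing_g)) abort(paste0("screened gene(s) absent from expression: ",
                                      paste(head(missing_g, 5), collapse = ", ")))
  x <- m[genes, , drop = FALSE]
  mu <- rowMeans(x)
  s <- row_sd_pop(x)
  if (any(s == 0)) abort("screened gene(s) with zero variance; rerun cox_screen on this cohort")
  z <- t((x - mu) / s)                      # samples x genes
  single <- length(genes) < 2
  if (single) {
    warn("fewer than 2 screened genes; DMS falls back to the single standardized gene")
    loadings <- matrix(c(1, 0), nrow = 1, dimnames = list(genes, c("PC1", "PC2")))
    scores <- cbind(z[, 1], 0)
    evar <- c(1, 0)
  } else {
    sv <- svd(z, nu = 2, nv = 2)
    rank2 <- sum(sv$d > sv$d[1] * 1e-10) >= 2
    if (!rank2) warn("standardized matrix is rank 1; PC2 set to 0")
    loadings <- sv$v
    dimnames(loadings) <- list(genes, c("PC1", "PC2"))
    scores <- z %*% loadings
    if (!rank2) {
      scores[, 2] <- 0
      loadings[, 2] <- 0
    }
    evar <- (sv$d[1:2]^2) / sum(sv$d^2)
  }

  # orientation anchored on protective genes (HR < 1); if none are known,
  # fall back to anti-risk orientation; if no HR at all, mean expression
  hr <- screen$hr[match(genes, screen$gene)]
  anchor <- if (any(!is.na(hr) & hr < 1)) {
    rowMeans(z[, !is.na(hr) & hr < 1, drop = FALSE])
  } else if (any(!is.na(hr) & hr > 1)) {
    -rowMeans(z[, !is.na(hr) & hr > 1, drop = FALSE])
  } else {
    rowMeans(z)
  }
  signs <- vapply(1:2, function(j) {
    if (all(scores[, j] == 0) || sd(scores[, j]) == 0 || sd(anchor) == 0) return(1)
    r <- cor(scores[, j], anchor)
    if (is.na(r) || r >= 0) 1 else -1
  }, numeric(1))

  sc <- tibble(
    sample_id = expr_samples(expr),
    pc1 = unname(signs[1] * scores[, 1]),
    pc2 = unname(signs[2] * scores[, 2])
  )
  sc$dms <- sc$pc1 + sc$pc2

  structure(list(
    genes = genes, center = mu, scale = s,
    loadings = loadings, explained_var = evar, signs = signs,
    scores = sc
  ), class = "dms_model")
}

#' Score a new cohort with a fitted DMS model
#'
#' Standardizes the new cohort's screened genes and projects them onto the
#' stored loadings. By default each gene is standardized with the *new*
#' cohort's own mean/SD (robust to cross-platform scale differences);
#' `train_scale = TRUE` reuses the training constants instead. Screened genes
#' absent from the new cohort are imputed at z = 0 and counted; at least
#' `min_gene_frac` of the model genes must be present.
#'
#' @param model a `dms_model`.
#' @param expr_new expression tibble for the cohort to score.
#' @param train_scale standardize with the training means/SDs.
#' @param min_gene_frac minimum fraction of model genes required.
#' @return tibble `sample_id`, `pc1`, `pc2`, `dms`; attribute
#'   `n_missing_genes`.
#' @export
apply_dms <- function(model, expr_new, train_scale = FALSE, min_gene_frac = 0.8) {
  stopifnot(inherits(model, "dms_model"))
  m <- expr_as_matrix(expr_new)
  present <- intersect(model$genes, rownames(m))
  if (length(present) < min_gene_frac * length(model$genes)) {
    abort(paste0("only ", length(present), "/", length(model$genes),
                 " model genes present (need >= ", round(100 * min_gene_frac), "%)"))
  }
  n_missing <- length(model$genes) - length(present)
  if (n_missing) inform(paste0(n_missing, " model gene(s) missing; imputed at z = 0"))
  x <- m[present, , drop = FALSE]
  if (train_scale) {
    mu <- model$center[present]; s <- model$scale[present]
  } else {
    mu <- rowMeans(x); s <- row_sd_pop(x)
    if (any(s == 0)) abort("model gene(s) constant in the new cohort; cannot standardize")
  }
  z <- t((x - mu) / s)                      # samples x present genes
  L <- model$loadings[present, , drop = FALSE]
  scores <- z %*% L                         # missing genes contribute 0
  out <- tibble(
    sample_id = expr_samples(expr_new),
    pc1 = unname(model$signs[1] * scores[, 1]),
    pc2 = unname(model$signs[2] * scores[, 2])
  )
  out$dms <- out$pc1 + out$pc2
  attr(out, "n_missing_genes") <- n_missing
  out
}

#' Dichotomize DMS scores at a cutpoint
#'
#' @param dms_scores tibble from [fit_dms()] (`$scores`) or [apply_dms()].
#' @param cutpoint numeric threshold; scores above it are `High_DMS`.
#' @return the tibble with a `group` factor column added.
#' @export
dms_groups <- function(dms_scores, cutpoint) {
  if (!all(c("sample_id", "dms") %in% names(dms_scores))) {
    abort("dms_scores must have sample_id and dms columns")
  }
  out <- dplyr::mutate(dms_scores,
    group = factor(ifelse(.data$dms > cutpoint, "High_DMS", "Low_DMS"),
                   levels = c("Low_DMS", "High_DMS")))
  if (nlevels(droplevels(out$group)) < 2) {
    warn("cutpoint leaves a degenerate grouping (one group empty)")
  }
  out
}

#' @export
print.dms_model <- function(x, ...) {
  cat("<dms_model> ", length(x$genes), " screened genes; explained variance PC1 = ",
      sprintf("%.1f%%", 100 * x$explained_var[1]), ", PC2 = ",
      sprintf("%.1f%%", 100 * x$explained_var[2]),
      "; orientation signs (", x$signs[1], ", ", x$signs[2], ")\n", sep = "")
  invisible(x)
}
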