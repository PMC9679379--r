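# End-to-end orchestration: simulate (or load) -> preprocess -> landscape ->
# consensus cluster -> DEG -> Cox screen + DMS -> survival split -> enrich.
# Every stage writes a TSV consumed by the next and logs a manifest row, so a
# run is auditable and byte-reproducible under a fixed seed.

#' Run the full subtype-and-score pipeline
#'
#' With `simulate = TRUE` (default) a synthetic cohort is generated from
#' `cohort_params`; otherwise supply `expression`, `clinical` and optionally
#' `mutations` / `cnv` tibbles (e.g. from the `read_*` loaders). Stages, in
#' order:
#'
#' 1. `simulate` — generate or ingest the cohort.
#' 2. `preprocess` — clinical follow-up filters (`min_days`), duplicate-gene
#'    collapse, sample alignment.
#' 3. `landscape` — regulator-panel mutation / CNV frequencies.
#' 4. `cluster` — consensus clustering on the panel genes; `chosen_k`
#'    overrides the delta-area recommendation.
#' 5. `deg` — moderated-t DEGs between the `contrast` clusters (defaults to
#'    clusters 2 vs 3 when k >= 3, else 1 vs 2).
#' 6. `score` — univariate Cox screen of the DEGs, then the PCA-based DMS.
#' 7. `survival` — maximally selected DMS cutpoint, High/Low KM curves,
#'    log-rank test, subtype x DMS-group crosstab.
#' 8. `enrich` — GSEA on the DEG ranking and hypergeometric ORA of the
#'    up/down lists against `gene_sets` (when `NULL`, synthetic random sets
#'    are built so the stage is still exercised; they are labelled
#'    `SYNTH_SET*`).
#'
#' @param out_dir output directory for all TSV artifacts.
#' @param seed master integer seed; per-stage seeds derive from it.
#' @param simulate generate a synthetic cohort.
#' @param cohort_params named list of [simulate_cohort()] arguments.
#' @param expression,clinical,mutations,cnv input tibbles when
#'   `simulate = FALSE`.
#' @param panel regulator panel tibble (`gene`, `role`).
#' @param gene_sets gene sets for enrichment ([read_gmt()] tibble or named
#'   list), or `NULL`.
#' @param k_range,reps,p_item consensus-clustering parameters.
#' @param chosen_k fixed number of subtypes (`NULL` = delta-area rule).
#' @param contrast length-2 cluster labels for the DEG stage.
#' @param min_days,p_cut,lfc_cut,cox_alpha,minprop stage thresholds.
#' @return list of class `pipeline_result` with every stage's objects plus
#'   `manifest`.
#' @export
run_pipeline <- function(out_dir, seed,
                         simulate = TRUE, cohort_params = list(),
                         expression = NULL, clinical = NULL,
                         mutations = NULL, cnv = NULL,
                         panel = default_regulator_panel(),
                         gene_sets = NULL,
                         k_range = 2:5, reps = 1000, p_item = 0.8,
                         chosen_k = NULL, contrast = NULL,
                         min_days = 30, p_cut = 0.05, lfc_cut = 1.0,
                         cox_alpha = 0.05, minprop = 0.1) {
  seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  log_stage <- function(stage, n_in, n_out, note = "") {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, n_in = n_in, n_out = n_out, seed = seed, note = note)
    inform(sprintf("[%s] in=%s out=%s %s", stage, n_in, n_out, note))
  }
  run_stage <- function(stage, code) {
    tryCatch(force(code), error = function(e) {
      abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }

  # 1 simulate / ingest ------------------------------------------------------
  cohort <- run_stage("simulate", {
    if (simulate) {
      cohort <- do.call(simulate_cohort, c(cohort_params, list(seed = seed)))
      write_cohort(cohort, file.path(out_dir, "cohort"))
      cohort
    } else {
      if (is.null(expression) || is.null(clinical)) {
        abort("supply expression and clinical tables when simulate = FALSE")
      }
      list(expression = expression, clinical = clinical,
           mutations = mutations, cnv = cnv)
    }
  })
  log_stage("simulate", NA_integer_, length(expr_samples(cohort$expression)),
            if (simulate) "synthetic cohort" else "user cohort")

  # 2 preprocess --------------------------------------------------------------
  bundle <- run_stage("preprocess", {
    clin <- filter_clinical_samples(cohort$clinical, min_days = min_days)
    expr <- collapse_duplicate_genes(cohort$expression)
    b <- align_cohort(expr, clin)
    write_result_tsv(b$expression, file.path(out_dir, "expression_clean.tsv"))
    write_result_tsv(b$clinical, file.path(out_dir, "clinical_clean.tsv"))
    write_result_tsv(dplyr::bind_rows(attr(clin, "exclusions"), b$exclusion_log |>
                       dplyr::transmute(rule = paste0("align_", .data$side),
                                        n_excluded = .data$n_dropped)),
                     file.path(out_dir, "exclusions.tsv"))
    b
  })
  log_stage("preprocess", nrow(cohort$clinical), nrow(bundle$clinical))

  # 3 landscape ---------------------------------------------------------------
  run_stage("landscape", {
    samples <- bundle$clinical$sample_id
    if (!is.null(cohort$mutations) && nrow(cohort$mutations)) {
      write_result_tsv(mutation_frequency(cohort$mutations, samples, panel),
                       file.path(out_dir, "mutation_frequency.tsv"))
    }
    if (!is.null(cohort$cnv)) {
      write_result_tsv(cnv_frequency(cohort$cnv, panel),
                       file.path(out_dir, "cnv_frequency.tsv"))
    }
    invisible(NULL)
  })
  log_stage("landscape", length(bundle$clinical$sample_id), nrow(panel))

  # 4 consensus cluster -------------------------------------------------------
  panel_genes <- intersect(panel$gene, bundle$expression$gene)
  if (length(panel_genes) < 2) abort("pipeline stage 'cluster' failed: fewer than 2 panel genes in the expression table")
  cons <- run_stage("cluster", {
    cc <- consensus_cluster(bundle$expression, features = panel_genes,
                            k_range = k_range, reps = reps, p_item = p_item,
                            seed = seed + 101L)
    write_result_tsv(cc$assignments, file.path(out_dir, "cluster_assignments.tsv"))
    write_result_tsv(cc$metrics, file.path(out_dir, "consensus_metrics.tsv"))
    cc
  })
  k_used <- chosen_k %||% select_k(cons)$chosen_k
  subtype <- cons$assignments[[paste0("k", k_used)]]
  log_stage("cluster", nrow(cons$assignments), k_used,
            paste0("k = ", k_used, if (is.null(chosen_k)) " (delta-area rule)" else " (user)"))

  # 5 deg ---------------------------------------------------------------------
  if (is.null(contrast)) {
    contrast <- if (k_used >= 3) c("2", "3") else c("1", "2")
  }
  degs <- run_stage("deg", {
    dt <- moderated_t(bundle$expression, as.character(subtype),
                      contrast = as.character(contrast))
    called <- call_degs(dt, p_cut = p_cut, lfc_cut = lfc_cut)
    write_result_tsv(called$table, file.path(out_dir, "deg_table.tsv"))
    called
  })
  log_stage("deg", nrow(degs$table), unname(degs$counts["total"]),
            paste0("contrast ", contrast[1], " vs ", contrast[2],
                   "; up=", degs$counts["up"], " down=", degs$counts["down"]))
  deg_genes <- c(degs$up, degs$down)
  if (!length(deg_genes)) abort("pipeline stage 'deg' failed: no genes pass the DEG thresholds")

  # 6 score -------------------------------------------------------------------
  dms <- run_stage("score", {
    screen <- cox_screen(bundle$expression, bundle$clinical,
                         candidate_genes = deg_genes, alpha = cox_alpha)
    if (!any(screen$screened)) abort("no DEG passes the Cox screen")
    model <- fit_dms(bundle$expression, screen)
    write_result_tsv(screen, file.path(out_dir, "cox_screen.tsv"))
    write_result_tsv(tidy(model), file.path(out_dir, "dms_loadings.tsv"))
    write_result_tsv(model$scores, file.path(out_dir, "dms_scores.tsv"))
    list(screen = screen, model = model)
  })
  log_stage("score", length(deg_genes), length(dms$model$genes),
            paste0("screened at p < ", cox_alpha))

  # 7 survival ----------------------------------------------------------------
  surv <- run_stage("survival", {
    sc <- dms$model$scores
    stopifnot(identical(sc$sample_id, bundle$clinical$sample_id))
    cp <- find_cutpoint(sc$dms, bundle$clinical$os_time,
                        bundle$clinical$os_status, minprop = minprop)
    grp <- dms_groups(sc, cp$cutpoint)
    lr <- logrank_test(bundle$clinical$os_time, bundle$clinical$os_status, grp$group)
    km_by <- lapply(split(seq_len(nrow(grp)), grp$group), function(i) {
      km_estimate(bundle$clinical$os_time[i], bundle$clinical$os_status[i])
    })
    med <- vapply(km_by, median_survival, numeric(1))
    summary_tbl <- tibble(
      group = names(km_by),
      n = as.numeric(table(grp$group)[names(km_by)]),
      median_survival = med
    ) |>
      dplyr::mutate(cutpoint = cp$cutpoint, logrank_chi2 = lr$chi2, logrank_p = lr$p)
    write_result_tsv(cp$scan, file.path(out_dir, "cutpoint_scan.tsv"))
    write_result_tsv(summary_tbl, file.path(out_dir, "survival_summary.tsv"))
    write_result_tsv(group_crosstab(subtype = as.character(subtype),
                                    dms_group = as.character(grp$group)),
                     file.path(out_dir, "group_crosstab.tsv"))
    list(cutpoint = cp, groups = grp, logrank = lr, km = km_by, summary = summary_tbl)
  })
  log_stage("survival", nrow(bundle$clinical), 2,
            sprintf("cutpoint=%.3f logrank p=%.3g", surv$cutpoint$cutpoint, surv$logrank$p))

  # 8 enrich ------------------------------------------------------------------
  enrich <- run_stage("enrich", {
    universe <- bundle$expression$gene
    gs <- gene_sets
    synthetic_sets <- is.null(gs)
    if (synthetic_sets) {
      gs <- with_seed_if(seed + 202L, {
        pool <- sample(universe)
        setNames(split(pool[seq_len(min(200, length(pool)))],
                       rep(1:10, length.out = min(200, length(pool)))),
                 sprintf("SYNTH_SET%02d", 1:10))
      })
    }
    stats <- setNames(degs$table$log2fc, degs$table$gene)
    gsea <- gsea_run(stats, gs, n_perm = 200, seed = seed + 303L)
    write_result_tsv(gsea, file.path(out_dir, "gsea.tsv"))
    ora_up <- if (length(degs$up)) ora_hypergeometric(degs$up, gs, universe) else NULL
    ora_down <- if (length(degs$down)) ora_hypergeometric(degs$down, gs, universe) else NULL
    if (!is.null(ora_up)) write_result_tsv(ora_up, file.path(out_dir, "ora_up.tsv"))
    if (!is.null(ora_down)) write_result_tsv(ora_down, file.path(out_dir, "ora_down.tsv"))
    list(gsea = gsea, ora_up = ora_up, ora_down = ora_down,
         synthetic_sets = synthetic_sets)
  })
  log_stage("enrich", length(deg_genes), nrow(enrich$gsea),
            if (enrich$synthetic_sets) "synthetic gene sets" else "user gene sets")

  manifest_tbl <- dplyr::bind_rows(manifest)
  write_result_tsv(manifest_tbl, file.path(out_dir, "manifest.tsv"))

  structure(list(
    cohort = cohort, bundle = bundle, consensus = cons, k = k_used,
    subtype = subtype, degs = degs, screen = dms$screen, dms_model = dms$model,
    survival = surv, enrichment = enrich, manifest = manifest_tbl,
    out_dir = out_dir, seed = seed
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", nrow(x$bundle$clinical), " samples, k = ", x$k,
      ", ", unname(x$degs$counts["total"]), " DEGs, ",
      length(x$dms_model$genes), " DMS genes; log-rank p = ",
      format(x$survival$logrank$p, digits = 3), "\n", sep = "")
  invisible(x)
}
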