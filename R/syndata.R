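# Synthetic-cohort generator. Every downstream stage (consensus clustering,
# DEG calling, Cox screening, DMS, survival split) is exercised against
# cohorts produced here, with full ground truth: true cluster labels, the
# latent prognostic score, and per-gene class flags.

#' Simulate a tumor cohort with planted subtype / DEG / survival structure
#'
#' The generator mirrors the statistical chain the analysis assumes:
#' * a small regulator panel whose per-gene cluster means are separated by
#'   `cluster_shift` (in units of `noise_sd`), giving `k_true` latent
#'   expression subtypes;
#' * a background gene block in which `n_deg_true` genes are shifted by
#'   `deg_log2fc` in one cluster each (cycling over clusters) — the "true
#'   DEGs" — and the rest are i.i.d. noise;
#' * a per-sample latent score: the standardized first principal direction of
#'   the true-DEG block;
#' * overall survival with proportional hazard
#'   `h_i = baseline_hazard * exp(-surv_beta * score_i)`, so a positive
#'   `surv_beta` makes a high latent score protective; independent
#'   exponential censoring is tuned so the expected censored fraction equals
#'   `censor_rate`;
#' * per-regulator mutation calls (Bernoulli at planted frequencies, default
#'   0.19/0.15/0.12 for the first three regulators then tapering to 0.02) and
#'   GISTIC-style CNV calls at planted gain/loss frequencies.
#'
#' Defaults emulate a mid-size glioma-like cohort: 143 samples, a 20-gene
#' regulator panel, 3 latent subtypes, survival on the scale of hundreds of
#' days.
#'
#' @param n_samples number of tumor samples (must be >= 3 * `k_true`).
#' @param n_regulators size of the regulator panel (symbols from
#'   [default_regulator_panel()] for the first 20).
#' @param n_background_genes background genes, including the true DEGs.
#' @param k_true number of latent expression clusters.
#' @param cluster_shift SD of per-gene cluster-mean offsets on the regulator
#'   panel, in units of `noise_sd`; 0 plants no cluster structure.
#' @param n_deg_true number of background genes truly differential between
#'   clusters.
#' @param deg_log2fc log2 fold change planted in each true DEG.
#' @param noise_sd residual SD of every gene.
#' @param surv_beta log-hazard decrease per unit latent score (>0: high score
#'   protective).
#' @param baseline_hazard baseline event hazard per day.
#' @param censor_rate target fraction of censored samples in `[0, 1]`.
#' @param surv_dist `"exponential"` (default) or `"weibull"` event times; both
#'   are proportional-hazards in the latent score.
#' @param weibull_shape shape parameter when `surv_dist = "weibull"`.
#' @param mut_freq optional numeric vector of planted per-regulator mutation
#'   frequencies (length `n_regulators`).
#' @param seed integer seed; identical configuration + seed reproduces the
#'   cohort exactly.
#' @return an object of class `synthetic_cohort`: a list with `expression`,
#'   `clinical`, `mutations`, `cnv`, `truth_samples`, `truth_genes`, `config`.
#' @export
simulate_cohort <- function(n_samples = 143, n_regulators = 20,
                            n_background_genes = 1000, k_true = 3,
                            cluster_shift = 1.5, n_deg_true = 100,
                            deg_log2fc = 1.5, noise_sd = 1,
                            surv_beta = 1, baseline_hazard = log(2) / 500,
                            censor_rate = 0.3,
                            surv_dist = c("exponential", "weibull"),
                            weibull_shape = 1.2, mut_freq = NULL, seed = NULL) {
  surv_dist <- match.arg(surv_dist)
  if (k_true < 1) abort("k_true must be >= 1")
  if (n_samples < 3 * k_true) abort("need n_samples >= 3 * k_true")
  if (n_deg_true > n_background_genes) abort("n_deg_true exceeds n_background_genes")
  if (censor_rate < 0 || censor_rate > 1) abort("censor_rate must be in [0, 1]")
  if (noise_sd <= 0) abort("noise_sd must be positive")

  panel <- default_regulator_panel()$gene
  reg_genes <- if (n_regulators <= length(panel)) head(panel, n_regulators) else {
    c(panel, sprintf("REG%02d", seq_len(n_regulators - length(panel)) + length(panel)))
  }
  bg_genes <- sprintf("G%05d", seq_len(n_background_genes))
  sample_ids <- sprintf("S%04d", seq_len(n_samples))

  with_seed_if(seed %||% stop_if_no_seed(), {
    cl <- sample(rep_len(seq_len(k_true), n_samples))

    sim_block <- function(genes, effect_fun) {
      if (!length(genes)) return(NULL)
      mu <- rnorm(length(genes), mean = 6, sd = 1.5)
      eff <- effect_fun(length(genes))             # genes x samples effect
      m <- mu + eff + matrix(rnorm(length(genes) * n_samples, sd = noise_sd),
                             nrow = length(genes))
      rownames(m) <- genes
      colnames(m) <- sample_ids
      m
    }

    reg_m <- sim_block(reg_genes, function(ng) {
      centers <- matrix(rnorm(ng * k_true, sd = cluster_shift * noise_sd), nrow = ng)
      centers[, cl, drop = FALSE]
    })

    deg_genes <- head(bg_genes, n_deg_true)
    up_cluster <- rep_len(seq_len(k_true), n_deg_true)
    deg_m <- sim_block(deg_genes, function(ng) {
      outer(seq_len(ng), cl, function(g, c) deg_log2fc * (up_cluster[g] == c))
    })

    null_genes <- setdiff(bg_genes, deg_genes)
    null_m <- sim_block(null_genes, function(ng) 0)

    m <- rbind(reg_m, deg_m, null_m)

    # latent score: standardized PC1 of the z-scored true-DEG block
    if (n_deg_true >= 2) {
      z <- (deg_m - rowMeans(deg_m)) / row_sd_pop(deg_m)
      sv <- svd(t(z), nu = 1, nv = 1)
      v1 <- sv$v[, 1]
      flip <- if (v1[which.max(abs(v1))] < 0) -1 else 1
      score <- as.numeric(sv$u[, 1]) * flip
      score <- (score - mean(score)) / sd(score)
    } else {
      score <- rep(0, n_samples)
    }

    h <- baseline_hazard * exp(-surv_beta * score)
    e1 <- rexp(n_samples)
    t_event <- switch(surv_dist,
      exponential = e1 / h,
      weibull = (e1 / h)^(1 / weibull_shape)
    )
    if (censor_rate <= 0) {
      os_time <- t_event; os_status <- rep(1, n_samples)
    } else if (censor_rate >= 1) {
      os_time <- rexp(n_samples, baseline_hazard); os_status <- rep(0, n_samples)
    } else {
      # independent censoring with the same PH form: P(censored_i) = hc/(hc+h_i)
      hc <- uniroot(function(lhc) mean(exp(lhc) / (exp(lhc) + h)) - censor_rate,
                    lower = log(min(h)) - 15, upper = log(max(h)) + 15)$root
      hc <- exp(hc)
      e2 <- rexp(n_samples)
      t_cens <- switch(surv_dist,
        exponential = e2 / hc,
        weibull = (e2 / hc)^(1 / weibull_shape)
      )
      os_status <- as.numeric(t_event <= t_cens)
      os_time <- pmin(t_event, t_cens)
    }

    if (is.null(mut_freq)) {
      mut_freq <- if (n_regulators >= 4) {
        c(0.19, 0.15, 0.12, seq(0.10, 0.02, length.out = n_regulators - 3))
      } else head(c(0.19, 0.15, 0.12), n_regulators)
    }
    if (length(mut_freq) != n_regulators) abort("mut_freq must have length n_regulators")
    mut_calls <- purrr::map2_dfr(reg_genes, mut_freq, function(g, f) {
      hit <- which(runif(n_samples) < f)
      if (!length(hit)) return(NULL)
      tibble(sample_id = sample_ids[hit], gene = g, variant_class = "Missense_Mutation")
    })
    if (!nrow(mut_calls)) {
      mut_calls <- tibble(sample_id = character(), gene = character(),
                          variant_class = character())
    }

    gain_freq <- if (n_regulators) seq(0.05, 0.25, length.out = n_regulators) else numeric()
    loss_freq <- if (n_regulators) seq(0.25, 0.05, length.out = n_regulators) else numeric()
    cnv <- NULL
    if (n_regulators) {
      cnv_m <- t(vapply(seq_len(n_regulators), function(i) {
        sample(c(-2L, -1L, 0L, 1L, 2L), n_samples, replace = TRUE,
               prob = c(0.3 * loss_freq[i], 0.7 * loss_freq[i],
                        1 - loss_freq[i] - gain_freq[i],
                        0.7 * gain_freq[i], 0.3 * gain_freq[i]))
      }, integer(n_samples)))
      rownames(cnv_m) <- reg_genes
      colnames(cnv_m) <- sample_ids
      cnv <- matrix_as_expr(cnv_m)
    }

    tmb <- as.numeric(table(factor(mut_calls$sample_id, levels = sample_ids)))
    clinical <- tibble(
      sample_id = sample_ids,
      os_time = os_time,
      os_status = os_status,
      IDH_mutant = rbinom(n_samples, 1, 0.1),
      tmb = tmb,
      cohort = "synthetic"
    )

    truth_genes <- tibble(
      gene = c(reg_genes, deg_genes, null_genes),
      class = c(rep("regulator", length(reg_genes)),
                rep("true_deg", length(deg_genes)),
                rep("null", length(null_genes))),
      up_cluster = c(rep(NA_integer_, length(reg_genes)), up_cluster,
                     rep(NA_integer_, length(null_genes))),
      mut_freq = c(mut_freq, rep(NA_real_, length(deg_genes) + length(null_genes))),
      cnv_gain_freq = c(gain_freq, rep(NA_real_, length(deg_genes) + length(null_genes))),
      cnv_loss_freq = c(loss_freq, rep(NA_real_, length(deg_genes) + length(null_genes)))
    )

    structure(list(
      expression = matrix_as_expr(m),
      clinical = clinical,
      mutations = mut_calls,
      cnv = cnv,
      truth_samples = tibble(sample_id = sample_ids, true_cluster = cl,
                             latent_score = score),
      truth_genes = truth_genes,
      config = list(n_samples = n_samples, n_regulators = n_regulators,
                    n_background_genes = n_background_genes, k_true = k_true,
                    cluster_shift = cluster_shift, n_deg_true = n_deg_true,
                    deg_log2fc = deg_log2fc, noise_sd = noise_sd,
                    surv_beta = surv_beta, baseline_hazard = baseline_hazard,
                    censor_rate = censor_rate, surv_dist = surv_dist,
                    weibull_shape = weibull_shape, seed = seed)
    ), class = "synthetic_cohort")
  })
}

stop_if_no_seed <- function() abort("simulate_cohort() requires an explicit integer `seed` for reproducibility")

#' Simulate a fully null cohort
#'
#' All genes i.i.d. noise, survival independent of expression. Used for
#' type-I-error calibration of the differential-expression and Cox screening
#' stages.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param seed integer seed.
#' @param censor_rate target censored fraction.
#' @return a `synthetic_cohort` (no regulator panel, no mutations/CNV).
#' @export
simulate_null_cohort <- function(n_samples = 100, n_genes = 5000, seed = NULL,
                                 censor_rate = 0.3) {
  simulate_cohort(n_samples = n_samples, n_regulators = 0,
                  n_background_genes = n_genes, k_true = 1,
                  cluster_shift = 0, n_deg_true = 0, deg_log2fc = 0,
                  surv_beta = 0, censor_rate = censor_rate, seed = seed)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat("<synthetic_cohort> ", cfg$n_samples, " samples, ",
      nrow(x$expression), " genes (", cfg$n_regulators, " regulators, ",
      cfg$n_deg_true, " true DEGs), k_true = ", cfg$k_true,
      ", seed = ", cfg$seed %||% NA, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Writes `expression.tsv`, `clinical.tsv`, `mutations.tsv`, `cnv.tsv`,
#' `truth_samples.tsv`, `truth_genes.tsv` — the on-disk form consumed by
#' [run_pipeline()] and readable with the `read_*` loaders.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_result_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  write_result_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_result_tsv(cohort$mutations, file.path(dir, "mutations.tsv"))
  if (!is.null(cohort$cnv)) write_result_tsv(cohort$cnv, file.path(dir, "cnv.tsv"))
  write_result_tsv(cohort$truth_samples, file.path(dir, "truth_samples.tsv"))
  write_result_tsv(cohort$truth_genes, file.path(dir, "truth_genes.tsv"))
  invisible(dir)
}
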