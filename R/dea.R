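# Two-group differential expression with empirical-Bayes moderated
# t-statistics: per-gene OLS fit, then shrinkage of the residual variances
# toward a common prior whose degrees of freedom and scale are estimated by
# moment matching on the log residual variances (digamma/trigamma scheme).

#' Moderated t-test between two sample groups
#'
#' Per gene: log2 fold change = mean(group A) - mean(group B); residual
#' variance `s_g^2` on `d_g = nA + nB - 2` df; prior `(d0, s0^2)` estimated by
#' matching the first two moments of `log s_g^2` (solving a trigamma equation
#' for d0); posterior variance
#' `s~_g^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)`; moderated
#' `t = log2FC / (s~_g * sqrt(1/nA + 1/nB))` referred to a t distribution on
#' `d0 + d_g` df. With `d0_override = 0` this is the ordinary pooled-variance
#' two-sample t-test; `d0_override = Inf` fully pools the variances.
#'
#' @param expr expression tibble (log2 scale).
#' @param group_labels two-level vector over samples; group A is
#'   `levels(factor(group_labels))[1]` unless `contrast` names the two levels
#'   as `c(A, B)`.
#' @param contrast optional length-2 character vector picking and ordering
#'   the two groups; samples in other groups are ignored.
#' @param d0_override optional prior df (0 = no moderation, Inf = full
#'   pooling); default estimates d0 from the data.
#' @return a `DEG table`: tibble per gene with `log2fc`, `t`, `df_total`,
#'   `p`, `p_adj` (BH), `direction`, `zero_variance` flag.
#' @export
moderated_t <- function(expr, group_labels, contrast = NULL, d0_override = NULL) {
  m <- expr_as_matrix(expr)
  g <- as.character(group_labels)
  if (length(g) != ncol(m)) abort("group_labels length must equal the number of samples")
  lev <- if (is.null(contrast)) levels(factor(g)) else as.character(contrast)
  if (length(lev) != 2) abort("exactly two groups are required (use `contrast` to pick two)")
  if (!all(lev %in% g)) abort("contrast level(s) absent from group_labels")
  keep <- g %in% lev
  m <- m[, keep, drop = FALSE]
  g <- g[keep]
  a <- g == lev[1]
  nA <- sum(a); nB <- sum(!a)
  if (nA < 2 || nB < 2) abort("each group needs at least 2 samples")

  mA <- rowMeans(m[, a, drop = FALSE])
  mB <- rowMeans(m[, !a, drop = FALSE])
  lfc <- mA - mB
  df_resid <- nA + nB - 2
  rss <- rowSums((m[, a, drop = FALSE] - mA)^2) +
         rowSums((m[, !a, drop = FALSE] - mB)^2)
  s2 <- rss / df_resid
  zero_var <- s2 <= 0

  if (is.null(d0_override)) {
    fit <- fit_var_prior(s2[!zero_var], df_resid)
    d0 <- fit$d0; s02 <- fit$s02
  } else {
    d0 <- d0_override
    s02 <- if (d0 > 0) mean(s2[!zero_var]) else 0
  }

  df_pooled <- df_resid * sum(!zero_var)   # information cap: pooled residual df
  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
    df_total <- rep(df_pooled, length(s2))
  } else {
    s2_post <- (d0 * s02 + df_resid * s2) / (d0 + df_resid)
    df_total <- rep(min(d0 + df_resid, df_pooled), length(s2))
  }
  se <- sqrt(s2_post * (1 / nA + 1 / nB))
  tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p <- 2 * pt(-abs(tstat), df = df_total)
  p[zero_var & lfc == 0] <- 1

  out <- tibble(
    gene = rownames(m),
    log2fc = lfc,
    t = tstat,
    df_total = df_total,
    p = p,
    p_adj = p.adjust(p, method = "BH"),
    direction = ifelse(lfc >= 0, "up_in_A", "up_in_B"),
    zero_variance = zero_var
  )
  attr(out, "groups") <- lev
  attr(out, "prior") <- list(d0 = d0, s02 = s02)
  out
}

# moment-matching fit of the scaled inverse-chi-square variance prior on
# log(s2): var(log s2) = trigamma(df/2) + trigamma(d0/2)
fit_var_prior <- function(s2, df_resid) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2) return(list(d0 = Inf, s02 = mean(s2)))
  e <- log(s2) - digamma(df_resid / 2) + log(df_resid / 2)
  ev <- mean((e - mean(e))^2) * length(e) / (length(e) - 1)
  excess <- ev - trigamma(df_resid / 2)
  if (excess <= 0) {
    # no excess dispersion in log s2: variances look fully pooled, and the
    # prior scale is the plain mean variance
    return(list(d0 = Inf, s02 = mean(s2)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton solve of trigamma(x) = y, y > 0
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Call DEGs from a moderated-t table
#'
#' Default rule: raw `p < p_cut` and `|log2FC| > lfc_cut` (both strict), the
#' conventional volcano-plot thresholds; `use_adjusted = TRUE` switches the p
#' filter to the BH-adjusted values.
#'
#' @param deg_table output of [moderated_t()].
#' @param p_cut p-value threshold (strict).
#' @param lfc_cut absolute log2 fold-change threshold (strict).
#' @param use_adjusted apply `p_cut` to `p_adj` instead of `p`.
#' @return list with `up` and `down` gene vectors (up = higher in group A),
#'   `table` (input plus `passes_threshold`), and `counts`.
#' @export
call_degs <- function(deg_table, p_cut = 0.05, lfc_cut = 1.0, use_adjusted = FALSE) {
  pv <- if (use_adjusted) deg_table$p_adj else deg_table$p
  pass <- pv < p_cut & abs(deg_table$log2fc) > lfc_cut
  tab <- dplyr::mutate(deg_table, passes_threshold = pass)
  up <- tab$gene[pass & tab$log2fc > 0]
  down <- tab$gene[pass & tab$log2fc < 0]
  list(up = up, down = down, table = tab,
       counts = c(total = sum(pass), up = length(up), down = length(down)))
}
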