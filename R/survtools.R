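# Survival stratification: Kaplan-Meier product-limit curves, median
# survival, log-rank comparison, and the maximally selected log-rank
# cutpoint that dichotomizes a continuous score (the "optimal cutoff" used
# for High/Low DMS groups).

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with Greenwood variance. Tied event times are
#' handled as simultaneous events at the shared time.
#'
#' @param times follow-up times (>= 0).
#' @param events event indicator (1 = death, 0 = censored).
#' @return tibble of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `greenwood_var` (one row per distinct observed time).
#' @export
km_estimate <- function(times, events) {
  check_surv(times, events)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1, conf.type = "none")
  gw <- sf$surv^2 * cumsum(ifelse(sf$n.risk > sf$n.event,
                                  sf$n.event / (sf$n.risk * (sf$n.risk - sf$n.event)),
                                  ifelse(sf$n.event > 0, Inf, 0)))
  gw[sf$surv == 0] <- 0
  out <- tibble(
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    n_censor = sf$n.censor, surv = sf$surv, greenwood_var = gw
  )
  class(out) <- c("km_curve", class(out))
  out
}

check_surv <- function(times, events) {
  if (length(times) != length(events)) abort("times and events must have equal length")
  if (anyNA(times) || anyNA(events)) abort("times/events must not contain missing values")
  if (any(times < 0)) abort("times must be non-negative")
  if (!all(events %in% c(0, 1))) abort("events must be 0/1")
  invisible(TRUE)
}

#' Median survival from a KM curve
#'
#' The smallest observed time at which the survival function drops to 0.5 or
#' below; `NA` when the curve never reaches 0.5.
#'
#' @param km a `km_curve` from [km_estimate()].
#' @return a single time, or `NA_real_`.
#' @export
median_survival <- function(km) {
  stopifnot(is.data.frame(km), all(c("time", "surv") %in% names(km)))
  hit <- which(km$surv <= 0.5)
  if (!length(hit)) return(NA_real_)
  km$time[hit[1]]
}

#' Log-rank test between k groups
#'
#' Observed-minus-expected chi-square with hypergeometric variance at each
#' event time, df = k - 1.
#'
#' @param times,events survival data.
#' @param groups group labels (2 or more levels).
#' @return tibble: `chi2`, `df`, `p`, `n_groups`.
#' @export
logrank_test <- function(times, events, groups) {
  check_surv(times, events)
  g <- factor(groups)
  if (nlevels(g) < 2) abort("need at least two groups")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1
  tibble(chi2 = unname(sd_$chisq), df = df,
         p = pchisq(unname(sd_$chisq), df, lower.tail = FALSE),
         n_groups = nlevels(g))
}

# standardized two-group log-rank statistic z = (O1 - E1)/sqrt(V1) for the
# split `high` (logical); vectorized over event times
logrank_z <- function(times, events, high) {
  et <- sort(unique(times[events == 1]))
  if (!length(et)) return(0)
  o1 <- e1 <- v1 <- 0
  for (t in et) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & high)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & high)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v1 <- v1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v1 <= 0) return(0)
  (o1 - e1) / sqrt(v1)
}

#' Maximally selected log-rank cutpoint for a continuous score
#'
#' Scans candidate cutpoints — midpoints between consecutive unique score
#' values that leave at least a `minprop` fraction of samples on each side —
#' and returns the one maximizing the absolute standardized two-group
#' log-rank statistic (ties broken toward the smaller cutpoint). The log-rank
#' p-value at the selected cutpoint is reported with a `selection_biased`
#' flag: after maximal selection the naive p is anti-conservative. Set
#' `n_perm > 0` for a permutation-adjusted p (the score vector is permuted
#' and the maximal |statistic| re-selected each time).
#'
#' @param score continuous per-sample score (e.g. DMS).
#' @param times,events survival data, same order as `score`.
#' @param minprop minimum fraction of samples per side.
#' @param n_perm permutations for the selection-adjusted p (0 = skip).
#' @param seed seed for the permutation null.
#' @return list of class `cutpoint_result`: `cutpoint`, `statistic`,
#'   `p_naive`, `selection_biased`, `p_perm` (NA unless requested), `scan`
#'   (tibble candidate/statistic/group sizes), `n_high`, `n_low`.
#' @export
find_cutpoint <- function(score, times, events, minprop = 0.1,
                          n_perm = 0, seed = NULL) {
  check_surv(times, events)
  if (length(score) != length(times)) abort("score length must match survival data")
  if (anyNA(score)) abort("score must not contain missing values")
  if (sum(events) == 0) abort("no events; a cutpoint cannot be selected")
  n <- length(score)
  u <- sort(unique(score))
  if (length(u) < 2) abort("all scores identical; no cutpoint exists")
  cands <- (head(u, -1) + tail(u, -1)) / 2
  keep <- vapply(cands, function(cp) {
    nl <- sum(score <= cp)
    nl / n >= minprop && (n - nl) / n >= minprop
  }, logical(1))
  cands <- cands[keep]
  if (!length(cands)) abort("no candidate cutpoint satisfies minprop on both sides")

  zs <- vapply(cands, function(cp) logrank_z(times, events, score > cp), numeric(1))
  best <- which(abs(zs) == max(abs(zs)))[1]   # ties -> smaller cutpoint

  chi2 <- zs[best]^2
  p_naive <- pchisq(chi2, df = 1, lower.tail = FALSE)
  p_perm <- NA_real_
  if (n_perm > 0) {
    obs <- abs(zs[best])
    exceed <- with_seed_if(seed %||% 1L, {
      vapply(seq_len(n_perm), function(b) {
        sp <- sample(score)
        zb <- vapply(cands, function(cp) logrank_z(times, events, sp > cp), numeric(1))
        max(abs(zb)) >= obs
      }, logical(1))
    })
    p_perm <- (1 + sum(exceed)) / (1 + n_perm)
  }

  structure(list(
    cutpoint = cands[best],
    statistic = zs[best],
    p_naive = p_naive,
    selection_biased = TRUE,
    p_perm = p_perm,
    scan = tibble(candidate = cands, statistic = zs,
                  n_low = vapply(cands, function(cp) sum(score <= cp), numeric(1)),
                  n_high = vapply(cands, function(cp) sum(score > cp), numeric(1))),
    n_low = sum(score <= cands[best]),
    n_high = sum(score > cands[best])
  ), class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat("<cutpoint_result> cutpoint = ", format(x$cutpoint, digits = 4),
      " (", x$n_low, " low / ", x$n_high, " high); |z| = ",
      format(abs(x$statistic), digits = 4),
      ", naive log-rank p = ", format(x$p_naive, digits = 3),
      " (selection-biased",
      if (!is.na(x$p_perm)) paste0("; permutation p = ", format(x$p_perm, digits = 3)),
      ")\n", sep = "")
  invisible(x)
}
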