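# ggplot2 views of the result objects. Every plot function returns the
# ggplot unevaluated so callers can restyle it.

#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(tibble(time = 0, surv = 1), object[, c("time", "surv")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for several groups on one panel
#'
#' @param times,events survival data.
#' @param groups group labels.
#' @return a ggplot.
#' @export
plot_km_groups <- function(times, events, groups) {
  g <- factor(groups)
  df <- purrr::map_dfr(levels(g), function(lv) {
    km <- km_estimate(times[g == lv], events[g == lv])
    dplyr::bind_rows(tibble(time = 0, surv = 1), km[, c("time", "surv")]) |>
      dplyr::mutate(group = lv)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot consensus_result
#' @export
autoplot.consensus_result <- function(object, ...) {
  ggplot2::ggplot(object$cdf, ggplot2::aes(x = .data$value, y = .data$cdf,
                                           colour = factor(.data$k))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Consensus value", y = "CDF", colour = "k") +
    ggplot2::theme_minimal()
}

#' @method autoplot cutpoint_result
#' @export
autoplot.cutpoint_result <- function(object, ...) {
  ggplot2::ggplot(object$scan, ggplot2::aes(x = .data$candidate,
                                            y = abs(.data$statistic))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutpoint, linetype = "dashed") +
    ggplot2::labs(x = "Candidate cutpoint", y = "|standardized log-rank statistic|") +
    ggplot2::theme_minimal()
}

#' @method autoplot dms_model
#' @export
autoplot.dms_model <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                              colour = .data$dms)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "PC1 (oriented)", y = "PC2 (oriented)", colour = "DMS") +
    ggplot2::theme_minimal()
}
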