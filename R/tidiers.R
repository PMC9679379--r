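# broom-style tidiers for the fitted objects.

#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, ...) {
  tidyr::pivot_longer(x$assignments, -"sample_id",
                      names_to = "k", names_prefix = "k",
                      names_transform = as.integer, values_to = "cluster")
}

#' @method glance consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  dplyr::mutate(x$metrics, reps = x$reps, p_item = x$p_item,
                distance = x$distance, seed = x$seed)
}

#' @method tidy dms_model
#' @export
tidy.dms_model <- function(x, ...) {
  tibble(gene = rownames(x$loadings),
         pc1_loading = x$loadings[, 1],
         pc2_loading = x$loadings[, 2],
         center = unname(x$center),
         scale = unname(x$scale))
}

#' @method glance dms_model
#' @export
glance.dms_model <- function(x, ...) {
  tibble(n_genes = length(x$genes),
         explained_var_pc1 = x$explained_var[1],
         explained_var_pc2 = x$explained_var[2],
         sign_pc1 = x$signs[1], sign_pc2 = x$signs[2])
}

#' @method tidy cutpoint_result
#' @export
tidy.cutpoint_result <- function(x, ...) x$scan

#' @method glance cutpoint_result
#' @export
glance.cutpoint_result <- function(x, ...) {
  tibble(cutpoint = x$cutpoint, statistic = x$statistic,
         p_naive = x$p_naive, selection_biased = x$selection_biased,
         p_perm = x$p_perm, n_low = x$n_low, n_high = x$n_high)
}
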