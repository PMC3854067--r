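#' Tidy a group summary
#'
#' Returns the pairwise comparison table in broom style: one row per group
#' pair with the raw and Bonferroni-adjusted p-value.
#'
#' @param x A `group_summary` from [summarize_groups()].
#' @param ... Unused.
#' @return A tibble: `group_1`, `group_2`, `p_raw`, `p_adj`, `significant`.
#' @export
tidy.group_summary <- function(x, ...) {
  x$pairwise
}

#' Glance at a group summary
#'
#' @param x A `group_summary` from [summarize_groups()].
#' @param ... Unused.
#' @return A one-row tibble: ANOVA `statistic`, `p.value`, `df`, `df.residual`
#'   (NA when the ANOVA was skipped), per-population counts and mean
#'   unloaded fractions in percent, and `alpha`.
#' @export
glance.group_summary <- function(x, ...) {
  g <- x$groups
  pick <- function(col, grp) {
    v <- g[[col]][g$group == grp]
    if (length(v)) v else NA_real_
  }
  tibble::tibble(
    statistic = if (is.null(x$anova)) NA_real_ else x$anova$f,
    p.value = if (is.null(x$anova)) NA_real_ else x$anova$p,
    df = if (is.null(x$anova)) NA_integer_ else x$anova$df1,
    df.residual = if (is.null(x$anova)) NA_integer_ else x$anova$df2,
    n_whole = pick("n", "whole"),
    n_high = pick("n", "high"),
    n_low = pick("n", "low"),
    mean_unloaded_pct_whole = pick("mean_unloaded_pct", "whole"),
    mean_unloaded_pct_high = pick("mean_unloaded_pct", "high"),
    mean_unloaded_pct_low = pick("mean_unloaded_pct", "low"),
    alpha = x$alpha)
}

#' Tidy a pipeline result
#'
#' @param x A `pipeline_result` from [run_pipeline()].
#' @param ... Unused.
#' @return The flat per-ROI table, see [roi_results_table()].
#' @export
tidy.pipeline_result <- function(x, ...) {
  roi_results_table(x)
}

#' Glance at a pipeline result
#'
#' @param x A `pipeline_result` from [run_pipeline()].
#' @param ... Unused.
#' @return One-row tibble combining stage counts with the group-summary
#'   glance.
#' @export
glance.pipeline_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_candidate_rois = x$metadata$n_candidate_rois,
                   n_quality_passed = x$metadata$n_quality_passed,
                   n_edge_removed = x$metadata$n_edge_removed,
                   n_final_rois = x$metadata$n_final_rois),
    glance(x$summary))
}
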