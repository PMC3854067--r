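#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one place. Defaults
#' follow the package's standard protocol: 12-px rolling ball, robust
#' destaining threshold at 4 MAD, ROI areas 5–400 px, quality thresholds
#' 0.002 F0/frame baseline slope, 0.05 baseline CV, 0.05 minimum unloading
#' extent, 10-frame tail window, ±20 px shift search.
#'
#' @param rolling_ball_radius Ball radius in px (default 12).
#' @param fm_background FM-stack background handling, see
#'   [subtract_stack_background()] (default `"static"`).
#' @param min_area_px,max_area_px,threshold_k,spot_sigma_px Segmentation
#'   parameters, see [build_candidate_mask()].
#' @param criteria A [quality_criteria()].
#' @param max_shift_px,min_peak_r Registration parameters, see
#'   [estimate_shift()].
#' @param qc_min_r,qc_slope_band Two-channel linearity QC thresholds, see
#'   [linearity_qc()].
#' @param group_channel Channel driving the IR grouping (default
#'   `"marker_a"`).
#' @param ir_method Immunoreactivity measurement: `"psf"` (default,
#'   matched-filter photometry at each ROI, see [psf_photometry()]) or
#'   `"sum"` (integrated density over the [dilate_rois()]-grown punctum
#'   region, local-background corrected).
#' @param ir_dilate_px Radius by which detection-core ROIs are grown (with
#'   proximity-resolved overlaps) into full-punctum regions for
#'   `ir_method = "sum"` (default 3, about two spot sigmas).
#' @param tail_window Trailing frames averaged as the plateau (default 10).
#' @param alpha Significance level for the group statistics (default 0.05).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(rolling_ball_radius = 12,
                            fm_background = "static",
                            min_area_px = 5L, max_area_px = 400L,
                            threshold_k = 4, spot_sigma_px = 1.5,
                            criteria = quality_criteria(),
                            max_shift_px = 20L, min_peak_r = 0.2,
                            qc_min_r = 0.5, qc_slope_band = c(0.5, 1.5),
                            group_channel = "marker_a",
                            ir_method = c("psf", "sum"), ir_dilate_px = 3L,
                            tail_window = 10L, alpha = 0.05) {
  ir_method <- match.arg(ir_method)
  structure(list(rolling_ball_radius = rolling_ball_radius,
                 fm_background = fm_background,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 threshold_k = threshold_k, spot_sigma_px = spot_sigma_px,
                 criteria = criteria,
                 max_shift_px = max_shift_px, min_peak_r = min_peak_r,
                 qc_min_r = qc_min_r, qc_slope_band = qc_slope_band,
                 group_channel = group_channel,
                 ir_method = ir_method, ir_dilate_px = ir_dilate_px,
                 tail_window = tail_window, alpha = alpha),
            class = "pipeline_config")
}

#' Run the full post-hoc correlation pipeline
#'
#' Executes, in order: FM background subtraction, bouton segmentation from
#' the destaining difference, kinetic quality filtering, rolling-ball
#' subtraction of the post-hoc channels, translation registration of each
#' channel to the FM baseline reference, removal of ROIs touching the
#' invalid border strips, integrated-density quantification with mean
#' normalization and high/low grouping, two-channel linearity QC, and the
#' group-segregated kinetics with ANOVA/Bonferroni statistics. Quality-failed
#' ROIs are excluded from all downstream analysis (flagged in the metadata).
#' Deterministic given its inputs.
#'
#' @param stack A [time_lapse_stack()] (raw).
#' @param channels Named list of one or two raw [channel_image()]s; the
#'   first (or `config$group_channel`) drives grouping.
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `rois` (final [roi_set()]),
#'   `quality` (verdicts for all candidate ROIs), `alignment` (per-channel
#'   transforms), `ir` (the [ir_table()]), `kinetics`
#'   ([compute_kinetics()] records), `summary` ([summarize_groups()]),
#'   `linearity` (QC tibble or NULL for single-channel runs), and
#'   `metadata` (stage-by-stage counts and settings).
#' @export
run_pipeline <- function(stack, channels, config = pipeline_config()) {
  stopifnot(inherits(stack, "time_lapse_stack"), length(channels) >= 1,
            !is.null(names(channels)))
  meta <- list(config = unclass_deep(config))

  # 1. FM background
  stack_bs <- subtract_stack_background(stack, config$rolling_ball_radius,
                                        config$fm_background)

  # 2. segmentation
  rois <- build_candidate_mask(stack_bs, config$min_area_px,
                               config$max_area_px, config$threshold_k,
                               config$spot_sigma_px, config$tail_window)
  meta$n_candidate_rois <- rois$n_rois

  # 3. kinetic quality filter (failed ROIs leave all downstream analysis)
  quality <- classify_roi_quality(stack_bs, rois, config$criteria)
  rois_q <- filter_rois(rois, quality$roi_id[quality$passed])
  meta$n_quality_passed <- rois_q$n_rois
  meta$quality_failed_excluded_everywhere <- TRUE

  # 4. rolling ball on the post-hoc channels
  channels_bs <- lapply(channels, function(ch) {
    rolling_ball_subtract(ch, config$rolling_ball_radius)$corrected
  })

  # 5. registration to the FM baseline reference
  reference <- rolling_ball_subtract(baseline_image(stack),
                                     config$rolling_ball_radius)$corrected
  alignment <- purrr::imap(channels_bs, function(ch, nm) {
    estimate_shift(reference, ch$pixels, config$max_shift_px,
                   config$min_peak_r, channel_name = nm)
  })
  channels_al <- purrr::map2(channels_bs, alignment, apply_shift)

  # 6. edge removal: every ROI whose immunoreactivity measurement support
  # (the full-punctum footprint plus the photometry window) reaches into
  # the invalid border strip is removed entirely
  margin <- if (config$ir_method == "psf") {
    # photometry window + refinement + peak-search reach
    ceiling(4 * config$spot_sigma_px) + 3L
  } else {
    config$ir_dilate_px
  }
  rois_ir <- dilate_rois(rois_q, config$ir_dilate_px)
  valid <- Reduce(`&`, lapply(channels_al, `[[`, "valid_mask"))
  valid_margin <- !max_filter(!valid, margin)
  bad <- sort(unique(rois_q$label_image[!valid_margin &
                                          rois_q$label_image > 0L]))
  keep <- setdiff(seq_len(rois_q$n_rois), bad)
  rois_ir_final <- filter_rois(rois_ir, keep)
  rois_final <- filter_rois(rois_q, keep)
  meta$n_edge_removed <- length(bad)
  meta$n_final_rois <- rois_final$n_rois
  if (rois_final$n_rois == 0L) {
    stop("pipeline stage edge-removal: no ROIs survive", call. = FALSE)
  }

  # 7. quantification, normalization, grouping
  group_channel <- if (config$group_channel %in% names(channels_al)) {
    config$group_channel
  } else names(channels_al)[1]
  ir <- if (config$ir_method == "psf") {
    ir_table(channels_al, rois_final, group_channel, method = "psf",
             spot_sigma_px = config$spot_sigma_px)
  } else {
    ir_table(channels_al, rois_ir_final, group_channel, method = "sum")
  }

  # 8. two-channel linearity QC
  linearity <- if (length(channels_al) >= 2L) {
    nms <- names(channels_al)[1:2]
    linearity_qc(ir[[paste0(nms[1], "_norm_ir")]],
                 ir[[paste0(nms[2], "_norm_ir")]],
                 config$qc_min_r, config$qc_slope_band)
  } else NULL

  # 9. kinetics + group statistics
  kinetics <- compute_kinetics(stack_bs, rois_final, config$tail_window)
  summary <- summarize_groups(kinetics, ir$group, config$alpha)

  meta$alignment <- lapply(alignment, function(a) {
    list(channel = a$channel_name, shift_row = a$shift_px[1],
         shift_col = a$shift_px[2], peak_correlation = a$peak_correlation,
         low_confidence = a$low_confidence)
  })
  meta$group_channel <- group_channel
  structure(list(rois = rois_final, quality = quality, alignment = alignment,
                 ir = ir, kinetics = kinetics, summary = summary,
                 linearity = linearity, metadata = meta),
            class = "pipeline_result")
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d ROIs (of %d candidates) analysed\n",
              x$metadata$n_final_rois, x$metadata$n_candidate_rois))
  print(x$summary)
  invisible(x)
}

#' Flat per-ROI result table of a pipeline run
#'
#' Joins the immunoreactivity table with the kinetic measurements into the
#' exportable per-ROI CSV layout.
#'
#' @param result A `pipeline_result`.
#' @return A tibble with one row per analysed ROI.
#' @export
roi_results_table <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  kin <- result$kinetics |>
    dplyr::select("roi_id", "f0", "unloaded_fraction", "unloaded_pct")
  dplyr::left_join(tibble::as_tibble(result$ir), kin, by = "roi_id")
}

#' Export a pipeline run to a directory
#'
#' Writes the per-ROI table, the group summary table, and the run metadata
#' (including alignment QC) via [write_results()].
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory.
#' @return The manifest tibble from [write_results()].
#' @export
export_pipeline <- function(result, out_dir) {
  meta <- result$metadata
  if (!is.null(result$linearity)) {
    meta$linearity_qc <- as.list(result$linearity)
  }
  if (!is.null(result$summary$anova)) {
    meta$anova <- result$summary$anova
  }
  write_results(list(roi_table = roi_results_table(result),
                     group_summary = result$summary$groups,
                     metadata = meta),
                out_dir)
}
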