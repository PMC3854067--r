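#' Bouton ROI set
#'
#' A labeled mask over the imaged field: 0 is background, k marks the pixels
#' of ROI k, labels consecutive `1..n_rois`. Constructed by
#' [build_candidate_mask()] or directly from any integer label matrix.
#'
#' @param label_image Integer matrix of labels (0 background).
#' @return An object of class `roi_set`: `label_image`, `n_rois`, and `info`,
#'   a tibble with `roi_id`, `area_px`, `centroid_row`, `centroid_col`, and
#'   bounding box columns.
#' @export
roi_set <- function(label_image) {
  stopifnot(is.matrix(label_image))
  storage.mode(label_image) <- "integer"
  labs <- sort(unique(label_image[label_image > 0L]))
  if (length(labs) > 0L && !identical(labs, seq_along(labs))) {
    # relabel consecutively, preserving order
    map <- integer(max(labs))
    map[labs] <- seq_along(labs)
    pos <- label_image > 0L
    label_image[pos] <- map[label_image[pos]]
  }
  n <- length(labs)
  if (n > 0L) {
    idx <- which(label_image > 0L)
    lab <- label_image[idx]
    r <- (idx - 1L) %% nrow(label_image) + 1L
    c_ <- (idx - 1L) %/% nrow(label_image) + 1L
    info <- tibble::tibble(roi_id = lab, r = r, c = c_) |>
      dplyr::group_by(.data$roi_id) |>
      dplyr::summarise(area_px = dplyr::n(),
                       centroid_row = mean(.data$r),
                       centroid_col = mean(.data$c),
                       bbox_rmin = min(.data$r), bbox_rmax = max(.data$r),
                       bbox_cmin = min(.data$c), bbox_cmax = max(.data$c),
                       .groups = "drop") |>
      dplyr::arrange(.data$roi_id)
  } else {
    info <- tibble::tibble(roi_id = integer(), area_px = integer(),
                           centroid_row = double(), centroid_col = double(),
                           bbox_rmin = integer(), bbox_rmax = integer(),
                           bbox_cmin = integer(), bbox_cmax = integer())
  }
  structure(list(label_image = label_image, n_rois = n, info = info),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs over %d x %d px\n", x$n_rois,
              nrow(x$label_image), ncol(x$label_image)))
  invisible(x)
}

# Shift-based max filter over a (2w+1)^2 square window (border handled by
# shrinking the window), used for local-maximum detection.
max_filter <- function(img, w) {
  out <- matrix(-Inf, nrow(img), ncol(img))
  nr <- nrow(img); nc <- ncol(img)
  for (dr in -w:w) {
    rs_src <- max(1, 1 + dr):min(nr, nr + dr)
    rs_dst <- rs_src - dr
    for (dc in -w:w) {
      cs_src <- max(1, 1 + dc):min(nc, nc + dc)
      cs_dst <- cs_src - dc
      out[rs_dst, cs_dst] <- pmax(out[rs_dst, cs_dst], img[rs_src, cs_src])
    }
  }
  out
}

# Isotropic Gaussian smoothing by separable convolution (reflected borders).
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  w <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-w):w)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_reflect <- function(m, w, rows = TRUE) {
    if (rows) rbind(m[w:1, , drop = FALSE], m, m[nrow(m):(nrow(m) - w + 1), , drop = FALSE])
    else cbind(m[, w:1, drop = FALSE], m, m[, ncol(m):(ncol(m) - w + 1), drop = FALSE])
  }
  conv_rows <- function(m) {
    p <- pad_reflect(m, w, rows = TRUE)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * p[j:(j + nrow(m) - 1), , drop = FALSE]
    }
    out
  }
  conv_cols <- function(m) {
    p <- pad_reflect(m, w, rows = FALSE)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * p[, j:(j + ncol(m) - 1), drop = FALSE]
    }
    out
  }
  conv_cols(conv_rows(img))
}

#' Destaining difference image of a stack
#'
#' Matched-filtered difference between the mean baseline image and the mean
#' tail (post-stimulus plateau) image: boutons that released dye appear as
#' bright spots, everything stationary cancels. The difference is smoothed
#' with a Gaussian at the expected spot sigma (a matched filter for
#' diffraction-limited puncta) before thresholding.
#'
#' @param stack A [time_lapse_stack()].
#' @param spot_sigma_px Expected spot sigma for the matched filter
#'   (default 1.5; 0 disables smoothing).
#' @param tail_window Trailing frames averaged as the plateau (default 10).
#' @return Numeric matrix.
#' @export
destain_difference <- function(stack, spot_sigma_px = 1.5, tail_window = 10L) {
  win <- frame_windows(stack, tail_window)
  base <- colMeans(stack$frames[win$baseline, , , drop = FALSE], dims = 1)
  tail_img <- colMeans(stack$frames[win$tail, , , drop = FALSE], dims = 1)
  gaussian_smooth(base - tail_img, spot_sigma_px)
}

# Greedy local-maxima seeds: candidate pixels are local maxima of D inside
# the binary mask; accepted in decreasing D order subject to a minimum
# separation, ties broken by smaller (row, col).
select_seeds <- function(D, binary, min_sep) {
  w <- max(1L, ceiling(min_sep / 2))
  is_max <- (D >= max_filter(D, w)) & binary
  idx <- which(is_max)
  if (length(idx) == 0L) return(NULL)
  r <- (idx - 1L) %% nrow(D) + 1L
  c_ <- (idx - 1L) %/% nrow(D) + 1L
  ord <- order(-D[idx], r, c_)
  r <- r[ord]; c_ <- c_[ord]
  keep_r <- numeric(0); keep_c <- numeric(0)
  for (i in seq_along(r)) {
    if (length(keep_r) > 0L) {
      d2 <- (keep_r - r[i])^2 + (keep_c - c_[i])^2
      if (min(d2) < min_sep^2) next
    }
    keep_r <- c(keep_r, r[i]); keep_c <- c(keep_c, c_[i])
  }
  cbind(row = keep_r, col = keep_c)
}

#' Build the candidate bouton mask from a destaining time-lapse
#'
#' Segments boutons as connected components of pixels whose destaining
#' difference exceeds a robust threshold `median(D) + threshold_k * mad(D)`,
#' splits touching puncta by seeded watershed on the difference image (seeds
#' are local maxima with minimum separation `2 * spot_sigma_px`), and keeps
#' components within the area bounds. ROI shapes follow the puncta.
#'
#' @param stack A [time_lapse_stack()]; should already be background
#'   subtracted (see [subtract_stack_background()]).
#' @param min_area_px,max_area_px Area bounds in pixels (defaults 5, 400).
#' @param threshold_k Robust threshold multiplier (default 4).
#' @param spot_sigma_px Expected spot sigma (default 1.5).
#' @param tail_window Trailing frames averaged as the plateau (default 10).
#' @return A [roi_set()]. Empty (with a warning) if no pixel clears the
#'   threshold.
#' @export
build_candidate_mask <- function(stack, min_area_px = 5L, max_area_px = 400L,
                                 threshold_k = 4, spot_sigma_px = 1.5,
                                 tail_window = 10L) {
  stopifnot(min_area_px >= 1, max_area_px >= min_area_px, threshold_k > 0)
  D <- destain_difference(stack, spot_sigma_px, tail_window)
  thr <- median(D) + threshold_k * mad(D)
  # floor for (near-)noise-free images, where mad(D) collapses to 0 and the
  # threshold would otherwise admit the entire Gaussian tail of every spot
  thr <- max(thr, median(D) + 0.01 * (max(D) - median(D)))
  binary <- D > thr
  if (!any(binary)) {
    warning("no pixels above the destaining threshold; empty ROI set")
    return(roi_set(matrix(0L, nrow(D), ncol(D))))
  }
  seeds <- select_seeds(D, binary, min_sep = 2 * max(spot_sigma_px, 1))
  if (is.null(seeds)) {
    warning("no watershed seeds found; empty ROI set")
    return(roi_set(matrix(0L, nrow(D), ncol(D))))
  }
  seed_img <- matrix(0L, nrow(D), ncol(D))
  seed_img[cbind(seeds[, 1], seeds[, 2])] <- seq_len(nrow(seeds))
  lab <- EBImage::propagate(D, seeds = seed_img, mask = binary)
  lab <- matrix(as.integer(lab), nrow(D), ncol(D))
  # area filter
  areas <- tabulate(lab[lab > 0L])
  drop <- which(areas < min_area_px | areas > max_area_px)
  if (length(drop) > 0L) lab[lab %in% drop] <- 0L
  roi_set(lab)
}

#' @importFrom stats mad
NULL

#' Kinetic quality criteria
#'
#' Thresholds for the three-parameter response classification: baseline
#' slope, baseline coefficient of variation, and extent of dye unloading.
#'
#' @param max_abs_baseline_slope Maximum |least-squares baseline slope| as a
#'   fraction of F0 per frame (default 0.002).
#' @param max_baseline_cv Maximum baseline sd/mean (default 0.05).
#' @param min_unloading_extent Minimum unloaded fraction of F0 (default 0.05).
#' @param tail_window_frames Trailing frames averaged as the plateau
#'   (default 10).
#' @return A list of class `quality_criteria`.
#' @export
quality_criteria <- function(max_abs_baseline_slope = 0.002,
                             max_baseline_cv = 0.05,
                             min_unloading_extent = 0.05,
                             tail_window_frames = 10L) {
  stopifnot(max_abs_baseline_slope > 0, max_baseline_cv > 0,
            min_unloading_extent > 0, tail_window_frames >= 1)
  structure(list(max_abs_baseline_slope = max_abs_baseline_slope,
                 max_baseline_cv = max_baseline_cv,
                 min_unloading_extent = min_unloading_extent,
                 tail_window_frames = as.integer(tail_window_frames)),
            class = "quality_criteria")
}

#' Per-ROI mean-intensity traces
#'
#' The ROI trace is the mean (not the sum) over the ROI's pixels in each
#' frame, so kinetic statistics are area-independent.
#'
#' @param stack A [time_lapse_stack()].
#' @param rois A [roi_set()] on the same geometry.
#' @return Numeric matrix, `n_rois x n_frames`; rownames are ROI ids.
#' @export
roi_traces <- function(stack, rois) {
  stopifnot(inherits(rois, "roi_set"))
  d <- dim(stack$frames)
  if (d[2] != nrow(rois$label_image) || d[3] != ncol(rois$label_image)) {
    stop("stack and roi_set geometries differ", call. = FALSE)
  }
  if (rois$n_rois == 0L) {
    return(matrix(0, 0, d[1]))
  }
  lab <- as.vector(rois$label_image)
  sel <- lab > 0L
  # frames as pixels x time
  mat <- matrix(aperm(stack$frames, c(2, 3, 1)), nrow = d[2] * d[3])
  sums <- rowsum(mat[sel, , drop = FALSE], lab[sel])
  areas <- tabulate(lab[sel], nbins = rois$n_rois)
  traces <- sums / areas
  rownames(traces) <- seq_len(rois$n_rois)
  traces
}

#' Classify the kinetic quality of each ROI
#'
#' Over each ROI's mean-intensity trace: `baseline_slope` is the
#' least-squares slope over the baseline frames divided by F0 (fraction of
#' F0 per frame), `baseline_cv` is sd/mean over the baseline frames, and
#' `unloading_extent` is `(F0 - mean(tail)) / F0`. An ROI passes when
#' |slope| and cv are at most their thresholds and the extent is at least
#' its threshold. All three statistics are ratios, so the verdict is
#' invariant to overall intensity scaling.
#'
#' @param stack A [time_lapse_stack()] (background subtracted).
#' @param rois A [roi_set()].
#' @param criteria A [quality_criteria()].
#' @return A tibble of class `quality_verdict`: `roi_id`, `f0`,
#'   `baseline_slope`, `baseline_cv`, `unloading_extent`, `passed`, and
#'   `failure_reasons` (comma-joined subset of `slope`, `cv`, `extent`).
#' @export
classify_roi_quality <- function(stack, rois, criteria = quality_criteria()) {
  stopifnot(inherits(criteria, "quality_criteria"))
  traces <- roi_traces(stack, rois)
  win <- frame_windows(stack, criteria$tail_window_frames)
  nb <- length(win$baseline)
  tt <- seq_len(nb)
  sxx <- sum((tt - mean(tt))^2)
  res <- purrr::map_dfr(seq_len(nrow(traces)), function(k) {
    tr <- traces[k, ]
    base <- tr[win$baseline]
    f0 <- mean(base)
    if (f0 <= 0) stop("ROI ", k, " has non-positive baseline F0", call. = FALSE)
    slope <- sum((tt - mean(tt)) * (base - mean(base))) / sxx / f0
    cv <- sd(base) / f0
    extent <- (f0 - mean(tr[win$tail])) / f0
    reasons <- c(if (abs(slope) > criteria$max_abs_baseline_slope) "slope",
                 if (cv > criteria$max_baseline_cv) "cv",
                 if (extent < criteria$min_unloading_extent) "extent")
    tibble::tibble(roi_id = as.integer(rownames(traces)[k]), f0 = f0,
                   baseline_slope = slope, baseline_cv = cv,
                   unloading_extent = extent,
                   passed = length(reasons) == 0L,
                   failure_reasons = paste(reasons, collapse = ","))
  })
  class(res) <- c("quality_verdict", class(res))
  res
}

#' Keep only the ROIs listed as passing
#'
#' @param rois A [roi_set()].
#' @param keep_ids Integer ROI ids to retain; remaining ROIs are relabeled
#'   consecutively.
#' @return A [roi_set()] with an attribute `removed_ids` recording the
#'   dropped original labels. The mapping from new to old ids is in
#'   `attr(, "original_ids")`.
#' @export
filter_rois <- function(rois, keep_ids) {
  lab <- rois$label_image
  drop <- setdiff(seq_len(rois$n_rois), keep_ids)
  lab[lab %in% drop] <- 0L
  out <- roi_set(lab)
  attr(out, "removed_ids") <- as.integer(drop)
  attr(out, "original_ids") <- sort(as.integer(keep_ids))
  out
}

#' Dilate ROIs into non-overlapping measurement regions
#'
#' Grows every ROI outward by `radius_px`, resolving contested pixels by
#' proximity (seeded region growing), so the result is again a disjoint
#' label image. Used to measure immunoreactivity over the full punctum
#' rather than only the detection core: with a margin of about two spot
#' sigmas the captured fraction of a punctum's integrated intensity is
#' nearly identical for dim and bright boutons, which keeps integrated
#' densities proportional to true marker levels.
#'
#' @param rois A [roi_set()].
#' @param radius_px Dilation radius in pixels (default 3).
#' @return A [roi_set()] with the same labels covering the grown regions.
#' @export
dilate_rois <- function(rois, radius_px = 3L) {
  stopifnot(inherits(rois, "roi_set"), radius_px >= 0)
  if (radius_px == 0 || rois$n_rois == 0L) return(rois)
  lab <- rois$label_image
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, "disc")
  grown <- EBImage::dilate(lab > 0L, brush)
  out <- EBImage::propagate(matrix(0, nrow(lab), ncol(lab)), seeds = lab,
                            mask = grown > 0)
  roi_set(matrix(as.integer(out), nrow(lab), ncol(lab)))
}

#' Remove ROIs touching invalid pixels
#'
#' After registration the post-hoc channels lose a border strip; every ROI
#' with at least one pixel outside the combined valid region is removed
#' entirely and the rest are relabeled consecutively.
#'
#' @param rois A [roi_set()].
#' @param valid_mask Logical matrix, same shape as the label image
#'   (typically the intersection of all channels' valid masks).
#' @return A [roi_set()] with attributes `removed_ids` and `original_ids`
#'   as in [filter_rois()].
#' @export
remove_edge_rois <- function(rois, valid_mask) {
  stopifnot(is.logical(valid_mask),
            all(dim(valid_mask) == dim(rois$label_image)))
  bad <- sort(unique(rois$label_image[!valid_mask & rois$label_image > 0L]))
  filter_rois(rois, setdiff(seq_len(rois$n_rois), bad))
}
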