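#' Estimate the translation aligning a channel to the FM reference
#'
#' Exhaustive search over integer displacements within `±max_shift_px`,
#' maximizing the normalized (Pearson) cross-correlation over the overlap
#' region. The returned `shift_px = (row, col)` is the displacement of the
#' moving image relative to the reference: `moving[r, c] ≈ reference[r -
#' shift_row, c - shift_col]`. Ties are broken by smaller `|row| + |col|`,
#' then smaller row, then smaller col.
#'
#' @param reference 2-D numeric matrix (typically the background-subtracted
#'   [baseline_image()] of the FM stack).
#' @param moving 2-D numeric matrix of the same shape (background
#'   subtracted).
#' @param max_shift_px Search half-width in pixels (default 20).
#' @param min_peak_r Peak correlation below this floor flags the transform
#'   as low-confidence with a warning (default 0.2).
#' @param channel_name Label carried on the transform.
#' @return A list of class `alignment_transform`: `shift_px` (integer row,
#'   col), `peak_correlation`, `channel_name`, `low_confidence`.
#' @export
estimate_shift <- function(reference, moving, max_shift_px = 20L,
                           min_peak_r = 0.2, channel_name = "channel") {
  stopifnot(is.matrix(reference), is.matrix(moving),
            all(dim(reference) == dim(moving)), max_shift_px >= 0)
  if (sd(reference) == 0 || sd(moving) == 0) {
    stop("cannot register a constant (zero-variance) image", call. = FALSE)
  }
  surf <- ncc_shift_surface(reference, moving, as.integer(max_shift_px))
  if (all(is.na(surf))) stop("no valid overlap in shift search", call. = FALSE)
  best <- max(surf, na.rm = TRUE)
  cand <- which(surf >= best - 1e-12, arr.ind = TRUE)
  dr <- cand[, 1] - max_shift_px - 1L
  dc <- cand[, 2] - max_shift_px - 1L
  ord <- order(abs(dr) + abs(dc), dr, dc)
  shift <- c(dr[ord[1]], dc[ord[1]])
  low <- best < min_peak_r
  if (low) {
    warning(sprintf("peak correlation %.3f below floor %.3f for '%s'",
                    best, min_peak_r, channel_name))
  }
  structure(list(shift_px = as.integer(shift), peak_correlation = best,
                 channel_name = channel_name, low_confidence = low),
            class = "alignment_transform")
}

#' @export
print.alignment_transform <- function(x, ...) {
  cat(sprintf("<alignment_transform> '%s' shift (%d, %d), peak r = %.4f%s\n",
              x$channel_name, x$shift_px[1], x$shift_px[2],
              x$peak_correlation,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Apply an alignment transform to a channel image
#'
#' Translates the moving image by minus the estimated shift so that it lands
#' on reference coordinates. Pixels with no source data (the border strip
#' that slid out of frame) are set to 0 and marked `FALSE` in the valid
#' mask; no extrapolation is performed.
#'
#' @param image A [channel_image()].
#' @param transform An `alignment_transform` from [estimate_shift()].
#' @return The aligned [channel_image()].
#' @export
apply_shift <- function(image, transform) {
  stopifnot(inherits(image, "channel_image"),
            inherits(transform, "alignment_transform"))
  dr <- transform$shift_px[1]
  dc <- transform$shift_px[2]
  px <- image$pixels
  vm <- image$valid_mask
  nr <- nrow(px); nc <- ncol(px)
  out <- matrix(0, nr, nc)
  out_valid <- matrix(FALSE, nr, nc)
  # aligned(r, c) = moving(r + dr, c + dc)
  r_dst <- max(1, 1 - dr):min(nr, nr - dr)
  c_dst <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(r_dst) > 0 && length(c_dst) > 0) {
    out[r_dst, c_dst] <- px[r_dst + dr, c_dst + dc]
    out_valid[r_dst, c_dst] <- vm[r_dst + dr, c_dst + dc]
  }
  channel_image(out, channel_name = image$channel_name, valid_mask = out_valid)
}

#' Two-channel linearity quality control
#'
#' Regresses the normalized immunoreactivity of one channel on the other
#' over matched ROIs. A slope close to 1 with a strong positive correlation
#' indicates a valid experiment (both channels report the same structures
#' with proportional intensity).
#'
#' @param ir_a,ir_b Equal-length numeric vectors of per-ROI normalized
#'   immunoreactivity (length at least 3).
#' @param min_r Minimum Pearson correlation to pass (default 0.5).
#' @param slope_band Admissible `(lo, hi)` slope interval (default
#'   `c(0.5, 1.5)`).
#' @return A one-row tibble: `slope`, `intercept`, `pearson_r`, `n`,
#'   `passed`.
#' @export
linearity_qc <- function(ir_a, ir_b, min_r = 0.5, slope_band = c(0.5, 1.5)) {
  stopifnot(length(ir_a) == length(ir_b), length(ir_a) >= 3)
  if (sd(ir_a) == 0) stop("zero variance in channel A values", call. = FALSE)
  fit <- lm(ir_b ~ ir_a)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  r <- stats::cor(ir_a, ir_b)
  tibble::tibble(slope = slope, intercept = intercept, pearson_r = r,
                 n = length(ir_a),
                 passed = slope >= slope_band[1] & slope <= slope_band[2] &
                   r >= min_r)
}
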