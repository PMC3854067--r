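#' Acquisition timing metadata for a destaining time-lapse
#'
#' Timing is always supplied explicitly; it is never inferred from pixel
#' content. `stim_start_frame` counts the frames acquired before stimulation
#' onset, so with the default 30-frame baseline the first stimulated frame is
#' R index 31.
#'
#' @param n_baseline_frames Number of pre-stimulus frames used to define the
#'   baseline (default 30, i.e. 30 s at 1 Hz).
#' @param stim_start_frame Frames acquired before stimulation onset; must be
#'   at least `n_baseline_frames`. Defaults to `n_baseline_frames`.
#' @param stim_duration_frames Duration of the high-potassium stimulation in
#'   frames (default 10).
#' @param frame_rate_hz Acquisition rate in frames per second (default 1).
#' @param bit_depth Camera bit depth; metadata only, no clipping is applied
#'   (default 14).
#' @return A list of class `stack_timing`.
#' @export
stack_timing <- function(n_baseline_frames = 30L,
                         stim_start_frame = n_baseline_frames,
                         stim_duration_frames = 10L,
                         frame_rate_hz = 1,
                         bit_depth = 14L) {
  stopifnot(n_baseline_frames >= 1, stim_duration_frames >= 1,
            frame_rate_hz > 0, bit_depth >= 1)
  if (stim_start_frame < n_baseline_frames) {
    stop("stim_start_frame must be >= n_baseline_frames", call. = FALSE)
  }
  structure(
    list(n_baseline_frames = as.integer(n_baseline_frames),
         stim_start_frame = as.integer(stim_start_frame),
         stim_duration_frames = as.integer(stim_duration_frames),
         frame_rate_hz = frame_rate_hz,
         bit_depth = as.integer(bit_depth)),
    class = "stack_timing")
}

#' Construct a time-lapse stack from a frame array and timing
#'
#' @param frames 3-D numeric array, `time x rows x cols`, non-negative.
#' @param timing A [stack_timing()] object.
#' @return An object of class `time_lapse_stack`: the frame array (promoted
#'   to double) plus timing metadata.
#' @export
time_lapse_stack <- function(frames, timing = stack_timing()) {
  stopifnot(inherits(timing, "stack_timing"))
  if (length(dim(frames)) != 3L) {
    stop("frames must be a 3-D array (time x rows x cols)", call. = FALSE)
  }
  if (any(!is.finite(frames))) stop("frames contain non-finite values", call. = FALSE)
  if (any(frames < 0)) stop("frames contain negative intensities", call. = FALSE)
  n_frames <- dim(frames)[1]
  needed <- timing$stim_start_frame + timing$stim_duration_frames + 1L
  if (n_frames < needed) {
    stop(sprintf("stack has %d frames but timing requires at least %d",
                 n_frames, needed), call. = FALSE)
  }
  is_int <- all(frames == round(frames))
  if (is_int && any(frames >= 2^timing$bit_depth)) {
    stop(sprintf("integer intensities reach or exceed 2^%d; check bit_depth",
                 timing$bit_depth), call. = FALSE)
  }
  storage.mode(frames) <- "double"
  structure(list(frames = frames, timing = timing),
            class = "time_lapse_stack")
}

#' @export
print.time_lapse_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<time_lapse_stack> %d frames of %d x %d px (%.3g Hz, baseline %d, stim %d+%d)\n",
    d[1], d[2], d[3], x$timing$frame_rate_hz, x$timing$n_baseline_frames,
    x$timing$stim_start_frame, x$timing$stim_duration_frames))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[1]

#' Indices of baseline and tail frames of a stack
#'
#' Baseline frames are `1:n_baseline_frames`; the tail window is the last
#' `tail_window` frames of the recording, used for the post-stimulus plateau.
#'
#' @param stack A `time_lapse_stack`.
#' @param tail_window Number of trailing frames in the tail window.
#' @return Integer vectors in a list with elements `baseline` and `tail`.
#' @export
frame_windows <- function(stack, tail_window = 10L) {
  nt <- n_frames(stack)
  stopifnot(tail_window >= 1, tail_window <= nt)
  list(baseline = seq_len(stack$timing$n_baseline_frames),
       tail = seq.int(nt - tail_window + 1L, nt))
}

#' Construct a single-channel immunofluorescence image
#'
#' @param pixels 2-D numeric matrix.
#' @param channel_name Label for the channel (e.g. `"marker_a"`).
#' @param valid_mask Logical matrix marking pixels with defined values; after
#'   registration border strips with no source data become `FALSE`. Defaults
#'   to all-`TRUE`.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel_name = "channel",
                          valid_mask = NULL) {
  stopifnot(is.matrix(pixels))
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  }
  stopifnot(is.logical(valid_mask), all(dim(valid_mask) == dim(pixels)))
  storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, channel_name = channel_name,
                 valid_mask = valid_mask),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> '%s' %d x %d px (%d invalid px)\n",
              x$channel_name, nrow(x$pixels), ncol(x$pixels),
              sum(!x$valid_mask)))
  invisible(x)
}

# -- TIFF layer ---------------------------------------------------------------
# Grayscale 16-bit storage: camera counts are integers, so the writer rounds
# to integer and requires values in [0, 65535]; read/write is then bit-exact.

read_tiff_frames <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  lapply(frames, function(f) {
    if (length(dim(f)) == 3L) {
      stop("RGB/multi-sample TIFF not supported; expected grayscale: ",
           path, call. = FALSE)
    }
    storage.mode(f) <- "double"
    f
  })
}

write_tiff_frames <- function(frames, path) {
  frames <- lapply(frames, function(f) {
    f <- round(f)
    if (any(f < 0) || any(f > 65535)) {
      stop("TIFF writer requires intensities in [0, 65535]", call. = FALSE)
    }
    f / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-frame grayscale TIFF time-lapse
#'
#' @param path Path to a multi-frame grayscale TIFF.
#' @param timing A [stack_timing()] object; timing is always explicit.
#' @return A [time_lapse_stack()].
#' @export
read_stack <- function(path, timing = stack_timing()) {
  frames <- read_tiff_frames(path)
  d <- dim(frames[[1]])
  arr <- array(0, c(length(frames), d[1], d[2]))
  for (t in seq_along(frames)) arr[t, , ] <- frames[[t]]
  time_lapse_stack(arr, timing)
}

#' Write a time-lapse stack as a multi-frame 16-bit grayscale TIFF
#'
#' @param stack A `time_lapse_stack` with integer-valued intensities in
#'   `[0, 65535]` (non-integer values are rounded).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  frames <- lapply(seq_len(n_frames(stack)), function(t) stack$frames[t, , ])
  write_tiff_frames(frames, path)
}

#' Read a single-frame grayscale TIFF immunofluorescence channel
#'
#' @param path Path to a single-frame grayscale TIFF.
#' @param channel_name Label to attach.
#' @return A [channel_image()] with an all-`TRUE` valid mask.
#' @export
read_channel <- function(path, channel_name = "channel") {
  frames <- read_tiff_frames(path)
  if (length(frames) != 1L) {
    stop(sprintf("expected a single-frame TIFF, found %d frames: %s",
                 length(frames), path), call. = FALSE)
  }
  channel_image(frames[[1]], channel_name = channel_name)
}

#' Write a channel image as a single-frame 16-bit grayscale TIFF
#'
#' @param channel A `channel_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_channel <- function(channel, path) {
  write_tiff_frames(list(channel$pixels), path)
}

#' Read or write a label mask TIFF
#'
#' Label masks are stored as single-frame 16-bit TIFF with 0 = background and
#' k = ROI k.
#'
#' @param path Path to the mask TIFF.
#' @return `read_label_mask`: an integer matrix. `write_label_mask`: `path`,
#'   invisibly.
#' @export
read_label_mask <- function(path) {
  frames <- read_tiff_frames(path)
  if (length(frames) != 1L) stop("label mask must be single-frame", call. = FALSE)
  m <- frames[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_label_mask
#' @param label_image Integer matrix of ROI labels.
#' @export
write_label_mask <- function(label_image, path) {
  write_tiff_frames(list(label_image), path)
}

#' Write pipeline result tables and run metadata to a directory
#'
#' Writes the per-ROI table and group-summary table as CSV and the run
#' metadata as JSON, and returns a manifest of what was written. Re-reading
#' the CSVs reproduces the values to full double precision.
#'
#' @param tables Named list with any of `roi_table` (data frame),
#'   `group_summary` (data frame), `metadata` (list, serialized as JSON).
#' @param out_dir Output directory, created if needed.
#' @return A tibble manifest: `file`, `type`, `n_rows` (NA for JSON).
#' @export
write_results <- function(tables, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir, call. = FALSE)
  manifest <- list()
  write_one <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(df, path)
    tibble::tibble(file = path, type = "csv", n_rows = nrow(df))
  }
  if (!is.null(tables$roi_table)) {
    manifest <- c(manifest, list(write_one(tables$roi_table, "roi_table")))
  }
  if (!is.null(tables$group_summary)) {
    manifest <- c(manifest, list(write_one(tables$group_summary, "group_summary")))
  }
  if (!is.null(tables$metadata)) {
    path <- file.path(out_dir, "run_metadata.json")
    jsonlite::write_json(tables$metadata, path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    manifest <- c(manifest,
                  list(tibble::tibble(file = path, type = "json",
                                      n_rows = NA_integer_)))
  }
  dplyr::bind_rows(manifest)
}
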