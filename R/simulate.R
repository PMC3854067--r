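#' Configuration for a synthetic FM1-43 destaining experiment
#'
#' Defaults emulate the acquisition protocol the pipeline is designed for:
#' 1 Hz imaging, a 30-frame baseline, a 10-frame high-potassium stimulation,
#' a 14-bit camera, diffraction-limited boutons rendered as isotropic
#' Gaussian spots, and post-hoc marker channels of the same field translated
#' by a small integer shift. See the package vignette for the rationale
#' behind each default.
#'
#' @param n_boutons Number of boutons to place (default 50).
#' @param image_shape `(rows, cols)` of every image (default `c(256, 256)`;
#'   full camera-scale 1004 x 1002 works but is slower).
#' @param n_frames Total frames in the time-lapse (default 90, i.e. 90 s).
#' @param psf_sigma_px Gaussian spot sigma in pixels (default 1.5).
#' @param brightness_log_mean,brightness_log_sd Lognormal parameters of the
#'   baseline integrated spot brightness (defaults `log(3000)`, 0.25).
#' @param unload_mean,unload_sd Mean and sd of the per-bouton unloading
#'   fraction, truncated to (0, 1) (defaults 0.34, 0.16).
#' @param unload_tau_frames Exponential destaining time constant during and
#'   after stimulation, in frames (default 4).
#' @param marker_base_level Median integrated marker-A spot intensity
#'   (default 1500).
#' @param marker_slope Planted linear dependence of marker-A level on the
#'   unloading fraction; 0 gives a null (Munc13-1-like) experiment, 1 a
#'   positive (RIM1-alpha-like) one (default 1).
#' @param marker_noise_cv Coefficient of variation of the mean-one lognormal
#'   bouton-to-bouton marker noise (default 0.8; reproduces realistically
#'   heavy-tailed immunoreactivity distributions).
#' @param channel_shift_px Integer `(row, col)` translation applied to both
#'   post-hoc channels relative to the functional image (default `c(3, -2)`).
#' @param min_separation_factor Minimum pairwise bouton separation in units
#'   of `psf_sigma_px` (default 4, the point at which neighbouring spots no
#'   longer merge; raise it to render effectively isolated boutons whose
#'   traces are free of neighbour-tail crosstalk).
#' @param background_level Flat background intensity added to every image
#'   (default 100).
#' @param background_gradient Peak-to-peak fractional diagonal gradient of
#'   the background plane (default 0.2).
#' @param noise_model `"gaussian"` or `"poisson"`.
#' @param noise_sd Gaussian read-noise sd (default 10; ignored for Poisson).
#' @param bleach_rate_per_frame Multiplicative photobleaching rate per frame
#'   (default 0).
#' @param n_baseline_frames,stim_duration_frames,frame_rate_hz,bit_depth
#'   Acquisition timing, as in [stack_timing()].
#' @param seed Integer seed; the same seed gives bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_boutons = 50L,
                       image_shape = c(256L, 256L),
                       n_frames = 90L,
                       psf_sigma_px = 1.5,
                       brightness_log_mean = log(3000),
                       brightness_log_sd = 0.25,
                       unload_mean = 0.34,
                       unload_sd = 0.16,
                       unload_tau_frames = 4,
                       marker_base_level = 1500,
                       marker_slope = 1,
                       marker_noise_cv = 0.8,
                       channel_shift_px = c(3L, -2L),
                       min_separation_factor = 4,
                       background_level = 100,
                       background_gradient = 0.2,
                       noise_model = c("gaussian", "poisson"),
                       noise_sd = 10,
                       bleach_rate_per_frame = 0,
                       n_baseline_frames = 30L,
                       stim_duration_frames = 10L,
                       frame_rate_hz = 1,
                       bit_depth = 14L,
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_boutons >= 1, length(image_shape) == 2, n_frames >= 2,
            psf_sigma_px > 0, unload_mean > 0, unload_mean < 1,
            unload_sd >= 0, unload_tau_frames >= 0, marker_base_level > 0,
            marker_slope >= 0, marker_noise_cv >= 0, noise_sd >= 0,
            bleach_rate_per_frame >= 0, bleach_rate_per_frame < 1,
            length(channel_shift_px) == 2,
            all(channel_shift_px == round(channel_shift_px)),
            min_separation_factor >= 4)
  cfg <- list(n_boutons = as.integer(n_boutons),
              image_shape = as.integer(image_shape),
              n_frames = as.integer(n_frames),
              psf_sigma_px = psf_sigma_px,
              brightness_log_mean = brightness_log_mean,
              brightness_log_sd = brightness_log_sd,
              unload_mean = unload_mean, unload_sd = unload_sd,
              unload_tau_frames = unload_tau_frames,
              marker_base_level = marker_base_level,
              marker_slope = marker_slope,
              marker_noise_cv = marker_noise_cv,
              channel_shift_px = as.integer(channel_shift_px),
              min_separation_factor = min_separation_factor,
              background_level = background_level,
              background_gradient = background_gradient,
              noise_model = noise_model, noise_sd = noise_sd,
              bleach_rate_per_frame = bleach_rate_per_frame,
              n_baseline_frames = as.integer(n_baseline_frames),
              stim_duration_frames = as.integer(stim_duration_frames),
              frame_rate_hz = frame_rate_hz,
              bit_depth = as.integer(bit_depth),
              seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

# Mean-one lognormal multiplier with the given coefficient of variation.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Background plane: flat level plus a linear diagonal gradient whose
# peak-to-peak amplitude is `gradient` times the level.
background_plane <- function(shape, level, gradient) {
  r <- matrix(seq_len(shape[1]) / shape[1], shape[1], shape[2])
  c_ <- matrix(rep(seq_len(shape[2]) / shape[2], each = shape[1]),
               shape[1], shape[2])
  level * (1 + gradient * ((r + c_) / 2 - 0.5))
}

# Place bouton centers by bounded rejection sampling: margin from the
# border large enough that the full rendering window stays in-frame in both
# the functional and the shifted post-hoc channels; pairwise separation
# >= 4 sigma so spots never merge at ground-truth level.
place_boutons <- function(n, shape, sigma, shift, sep_factor = 4) {
  margin <- ceiling(6 * sigma) + max(abs(shift))
  min_sep <- sep_factor * sigma
  lo <- 1 + margin
  hi_r <- shape[1] - margin
  hi_c <- shape[2] - margin
  if (hi_r <= lo || hi_c <= lo) stop("image too small for bouton margin", call. = FALSE)
  rows <- numeric(n); cols <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 200L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf("could not place %d boutons with separation %.1f px", n,
                   min_sep), call. = FALSE)
    }
    r <- runif(1, lo, hi_r)
    c_ <- runif(1, lo, hi_c)
    if (placed > 0L) {
      d2 <- (rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - c_)^2
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1L
    rows[placed] <- r
    cols[placed] <- c_
  }
  cbind(row = rows, col = cols)
}

# Unit-mass Gaussian spot sampled on a (2w+1)^2 window around (cr, cc);
# normalized over the window so the rendered integral equals the requested
# level exactly.
spot_window <- function(cr, cc, sigma, shape) {
  w <- ceiling(6 * sigma)
  r0 <- round(cr); c0 <- round(cc)
  rs <- (r0 - w):(r0 + w)
  cs <- (c0 - w):(c0 + w)
  g <- exp(-outer((rs - cr)^2, (cs - cc)^2, "+") / (2 * sigma^2))
  list(rows = rs, cols = cs, values = g / sum(g))
}

# Per-frame multiplicative destaining model, frame index t = 1..n (R
# convention), stimulation onset after `stim_start` frames:
# 1 before onset, (1-u) + u * exp(-(t - onset)/tau) from onset on.
destain_model <- function(u, tau, stim_start, n_frames) {
  t0 <- seq_len(n_frames) - 1 # elapsed frames, 0-based
  dt <- t0 - stim_start
  decay <- ifelse(dt < 0, 1,
                  if (tau <= .Machine$double.eps) {
                    ifelse(dt == 0, 1, 0)
                  } else {
                    exp(-pmax(dt, 0) / tau)
                  })
  (1 - u) + u * decay
}

#' Nominal unloaded fraction of a noise-free simulated trace
#'
#' Closed-form value the kinetics stage should report for a noise-free,
#' bleach-free, background-free bouton: the baseline mean is the full
#' brightness and the tail mean follows the exponential destaining model, so
#' the unloaded fraction depends only on `u`, `tau_frames`, and the window
#' geometry. Used as the analytic oracle for kinetic exactness tests.
#'
#' @param u Planted unloading fraction in `[0, 1)`.
#' @param tau_frames Destaining time constant in frames.
#' @param stim_start Frames acquired before stimulation onset.
#' @param trace_end Total number of frames in the trace.
#' @param tail_window Number of trailing frames averaged as the plateau.
#' @return The unloaded fraction the pipeline should measure.
#' @export
nominal_unloaded_fraction <- function(u, tau_frames, stim_start, trace_end,
                                      tail_window) {
  stopifnot(trace_end > stim_start, tail_window >= 1,
            tail_window <= trace_end)
  model <- destain_model(u, tau_frames, stim_start, trace_end)
  tail_idx <- seq.int(trace_end - tail_window + 1L, trace_end)
  1 - mean(model[tail_idx]) # baseline mean is exactly 1
}

#' Simulate a complete FM1-43 + post-hoc immunofluorescence experiment
#'
#' Renders the destaining time-lapse and two marker channels of the same
#' field, with planted per-bouton unloading fractions and marker levels and
#' a known integer translation between the functional and post-hoc images.
#'
#' Per bouton `i` with baseline brightness `B_i` and unloading fraction
#' `u_i`, the noise-free trace is `B_i * b(t)` during the baseline and
#' `B_i * b(t) * ((1 - u_i) + u_i * exp(-(t - t_stim)/tau))` from
#' stimulation onset, with `b(t) = (1 - bleach_rate)^t`. Marker-A integrated
#' intensity is `marker_base_level * (1 + marker_slope*(u_i - unload_mean))`
#' times mean-one lognormal noise; marker-B is marker-A times independent
#' lognormal noise, so normalized B vs A has slope about 1 (the two-channel
#' linearity control). The truth table records the exact rendered integrated
#' levels, before background and pixel noise.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_experiment` with elements `stack`
#'   ([time_lapse_stack()]), `marker_a`, `marker_b` ([channel_image()]s),
#'   `truth` (tibble: `bouton`, `row`, `col`, `baseline_brightness`,
#'   `unload_fraction`, `marker_a_level`, `marker_b_level`), and `config`.
#'   The channel shift is also attached as `attr(truth, "channel_shift_px")`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  shape <- config$image_shape
  nb <- config$n_boutons
  nt <- config$n_frames
  stim_start <- config$n_baseline_frames

  centers <- place_boutons(nb, shape, config$psf_sigma_px,
                           config$channel_shift_px,
                           config$min_separation_factor)
  brightness <- rlnorm(nb, config$brightness_log_mean, config$brightness_log_sd)
  u <- rnorm(nb, config$unload_mean, config$unload_sd)
  # truncate to (0, 1) by resampling out-of-range draws
  for (iter in 1:100) {
    bad <- u <= 0 | u >= 1
    if (!any(bad)) break
    u[bad] <- rnorm(sum(bad), config$unload_mean, config$unload_sd)
  }
  u <- pmin(pmax(u, 1e-6), 1 - 1e-6)

  marker_a <- config$marker_base_level *
    (1 + config$marker_slope * (u - config$unload_mean)) *
    rlnorm_cv(nb, config$marker_noise_cv)
  marker_a <- pmax(marker_a, 0)
  marker_b <- marker_a * rlnorm_cv(nb, config$marker_noise_cv)

  npix <- shape[1] * shape[2]
  spots <- lapply(seq_len(nb), function(i) {
    spot_window(centers[i, 1], centers[i, 2], config$psf_sigma_px, shape)
  })
  # sparse pixel-by-bouton spot basis for the functional image
  sp_idx <- lapply(spots, function(s) {
    px <- outer(s$rows, (s$cols - 1) * shape[1], "+")
    list(px = as.vector(px), val = as.vector(s$values))
  })
  S <- Matrix::sparseMatrix(
    i = unlist(lapply(sp_idx, `[[`, "px")),
    j = rep(seq_len(nb), vapply(sp_idx, function(z) length(z$px), 1L)),
    x = unlist(lapply(sp_idx, `[[`, "val")),
    dims = c(npix, nb))

  bleach <- (1 - config$bleach_rate_per_frame)^(seq_len(nt) - 1)
  scales <- vapply(seq_len(nb), function(i) {
    brightness[i] * bleach * destain_model(u[i], config$unload_tau_frames,
                                           stim_start, nt)
  }, numeric(nt)) # nt x nb
  clean <- as.matrix(S %*% t(scales)) # npix x nt
  bg <- background_plane(shape, config$background_level,
                         config$background_gradient)
  clean <- clean + as.vector(bg)
  frames_mat <- add_pixel_noise(clean, config)
  frames <- aperm(array(frames_mat, c(shape[1], shape[2], nt)), c(3, 1, 2))

  render_channel <- function(levels, name) {
    img <- bg
    sh <- config$channel_shift_px
    for (i in seq_len(nb)) {
      s <- spots[[i]]
      img[s$rows + sh[1], s$cols + sh[2]] <-
        img[s$rows + sh[1], s$cols + sh[2]] + levels[i] * s$values
    }
    img <- matrix(add_pixel_noise(matrix(as.vector(img), ncol = 1), config),
                  shape[1], shape[2])
    channel_image(img, channel_name = name)
  }
  ch_a <- render_channel(marker_a, "marker_a")
  ch_b <- render_channel(marker_b, "marker_b")

  timing <- stack_timing(n_baseline_frames = config$n_baseline_frames,
                         stim_start_frame = stim_start,
                         stim_duration_frames = config$stim_duration_frames,
                         frame_rate_hz = config$frame_rate_hz,
                         bit_depth = config$bit_depth)
  truth <- tibble::tibble(
    bouton = seq_len(nb),
    row = centers[, 1], col = centers[, 2],
    baseline_brightness = brightness,
    unload_fraction = u,
    marker_a_level = marker_a,
    marker_b_level = marker_b)
  attr(truth, "channel_shift_px") <- config$channel_shift_px

  structure(list(stack = time_lapse_stack(frames, timing),
                 marker_a = ch_a, marker_b = ch_b,
                 truth = truth, config = config),
            class = "sim_experiment")
}

add_pixel_noise <- function(mat, config) {
  out <- switch(config$noise_model,
    gaussian = if (config$noise_sd > 0) {
      mat + rnorm(length(mat), 0, config$noise_sd)
    } else mat,
    poisson = matrix(rpois(length(mat), pmax(mat, 0)), nrow(mat), ncol(mat)))
  pmax(out, 0)
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("<sim_experiment> %d boutons, %d frames, %d x %d px, seed %d\n",
              x$config$n_boutons, x$config$n_frames, x$config$image_shape[1],
              x$config$image_shape[2], x$config$seed))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Writes the time-lapse stack and both marker channels as 16-bit TIFF, the
#' truth table as CSV, and the exact configuration as JSON.
#'
#' @param sim A `sim_experiment`.
#' @param out_dir Output directory, created if needed.
#' @return Tibble manifest of written files.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(stack = file.path(out_dir, "fm_stack.tif"),
             marker_a = file.path(out_dir, "marker_a.tif"),
             marker_b = file.path(out_dir, "marker_b.tif"),
             truth = file.path(out_dir, "truth.csv"),
             config = file.path(out_dir, "config.json"))
  write_stack(sim$stack, paths[["stack"]])
  write_channel(sim$marker_a, paths[["marker_a"]])
  write_channel(sim$marker_b, paths[["marker_b"]])
  truth <- sim$truth
  truth$channel_shift_row <- attr(sim$truth, "channel_shift_px")[1]
  truth$channel_shift_col <- attr(sim$truth, "channel_shift_px")[2]
  readr::write_csv(truth, paths[["truth"]])
  jsonlite::write_json(unclass(sim$config), paths[["config"]],
                       auto_unbox = TRUE, digits = NA)
  tibble::tibble(artifact = names(paths), file = unname(paths))
}
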