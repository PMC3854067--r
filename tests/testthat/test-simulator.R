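small_cfg <- function(...) {
  sim_config(n_boutons = 12, image_shape = c(96, 96), ...)
}

test_that("the same seed reproduces the experiment bit-identically", {
  a <- simulate_experiment(small_cfg(seed = 5))
  b <- simulate_experiment(small_cfg(seed = 5))
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$marker_a$pixels, b$marker_a$pixels)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_experiment(small_cfg(seed = 6))
  expect_false(identical(a$stack$frames, c_$stack$frames))
})

test_that("zero marker slope and noise gives identical marker levels", {
  sim <- simulate_experiment(small_cfg(marker_slope = 0, marker_noise_cv = 0,
                                       seed = 2))
  expect_true(all(abs(sim$truth$marker_a_level -
                        sim$truth$marker_a_level[1]) < 1e-9))
})

test_that("a noise-free trace plateaus at (1 - u) * brightness", {
  sim <- simulate_experiment(sim_config(
    n_boutons = 1, image_shape = c(64, 64), unload_mean = 0.4, unload_sd = 0,
    unload_tau_frames = 3, noise_sd = 0, background_level = 0,
    background_gradient = 0, bleach_rate_per_frame = 0, seed = 3))
  per_frame_sum <- apply(sim$stack$frames, 1, sum)
  B <- sim$truth$baseline_brightness
  expect_equal(per_frame_sum[1], B, tolerance = 1e-9)
  # 60 frames past stimulation with tau = 3: decay term is ~exp(-59/3) ~ 0
  expect_equal(per_frame_sum[90], 0.6 * B, tolerance = 1e-6)
})

test_that("truth marker levels equal the noise-free integrated intensities", {
  sim <- simulate_experiment(small_cfg(noise_sd = 0, background_level = 0,
                                       background_gradient = 0, seed = 4))
  expect_equal(sum(sim$marker_a$pixels), sum(sim$truth$marker_a_level),
               tolerance = 1e-6)
  expect_equal(sum(sim$marker_b$pixels), sum(sim$truth$marker_b_level),
               tolerance = 1e-6)
})

test_that("with zero channel shift, FM and marker centroids coincide", {
  # well-isolated boutons: neighbour Gaussian tails would otherwise bias
  # the intensity-weighted centroids at the sub-0.1 px level
  sim <- simulate_experiment(small_cfg(noise_sd = 0, background_level = 0,
                                       background_gradient = 0,
                                       channel_shift_px = c(0, 0),
                                       min_separation_factor = 12, seed = 8))
  base <- baseline_image(sim$stack)
  centroid <- function(img, cr, cc, w = 6) {
    rs <- (round(cr) - w):(round(cr) + w)
    cs <- (round(cc) - w):(round(cc) + w)
    win <- img[rs, cs]
    c(sum(rs * rowSums(win)) / sum(win), sum(cs * colSums(win)) / sum(win))
  }
  for (i in seq_len(nrow(sim$truth))) {
    c_fm <- centroid(base, sim$truth$row[i], sim$truth$col[i])
    c_a <- centroid(sim$marker_a$pixels, sim$truth$row[i], sim$truth$col[i])
    expect_lt(max(abs(c_fm - c_a)), 0.1)
  }
})

test_that("planted unloading fractions stay in (0, 1) and respect the seed", {
  sim <- simulate_experiment(small_cfg(unload_sd = 0.3, seed = 9))
  expect_true(all(sim$truth$unload_fraction > 0 &
                    sim$truth$unload_fraction < 1))
})

test_that("boutons keep their minimum separation and an infeasible packing errors", {
  sim <- simulate_experiment(small_cfg(seed = 10))
  d <- as.matrix(dist(sim$truth[, c("row", "col")]))
  diag(d) <- Inf
  expect_gte(min(d), 4 * sim$config$psf_sigma_px)
  expect_error(
    simulate_experiment(sim_config(n_boutons = 2000, image_shape = c(64, 64))),
    "could not place")
})

test_that("nominal unloaded fraction matches the closed-form trace model", {
  expect_equal(nominal_unloaded_fraction(0, 4, 30, 90, 10), 0)
  # instantaneous destaining: the full planted fraction is recovered
  expect_equal(nominal_unloaded_fraction(0.4, 0, 30, 90, 10), 0.4)
  # tau = 5, tail = last 10 of 60 post-stimulus frames: direct evaluation
  u <- 0.4; tau <- 5; stim <- 30; n <- 90; tw <- 10
  t0 <- (n - tw):(n - 1) # 0-based tail frame indices
  expected <- 1 - mean((1 - u) + u * exp(-(t0 - stim) / tau))
  expect_equal(nominal_unloaded_fraction(u, tau, stim, n, tw), expected,
               tolerance = 1e-12)
})

test_that("population-mean nominal unloading increases with unload_mean", {
  mean_uf <- function(um) {
    set.seed(42)
    u <- pmin(pmax(rnorm(500, um, 0.1), 1e-6), 1 - 1e-6)
    mean(vapply(u, nominal_unloaded_fraction, 1, tau_frames = 4,
                stim_start = 30, trace_end = 90, tail_window = 10))
  }
  ufs <- vapply(c(0.2, 0.34, 0.5, 0.7), mean_uf, 1)
  expect_true(all(diff(ufs) > 0))
})

test_that("write_simulation exports stack, channels, truth and config", {
  out_dir <- withr::local_tempdir()
  sim <- simulate_experiment(small_cfg(seed = 12))
  manifest <- write_simulation(sim, out_dir)
  expect_setequal(manifest$artifact,
                  c("stack", "marker_a", "marker_b", "truth", "config"))
  expect_true(all(file.exists(manifest$file)))
  cfg <- jsonlite::read_json(file.path(out_dir, "config.json"))
  expect_equal(cfg$n_boutons, 12)
  truth <- readr::read_csv(file.path(out_dir, "truth.csv"),
                           show_col_types = FALSE)
  expect_equal(nrow(truth), 12)
  stack <- read_stack(file.path(out_dir, "fm_stack.tif"))
  expect_equal(dim(stack$frames), c(90, 96, 96))
})
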