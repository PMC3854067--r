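test_that("noise-free simulation is segmented into exactly the planted boutons", {
  sim <- simulate_experiment(sim_config(noise_sd = 0, seed = 21))
  stk <- subtract_stack_background(sim$stack)
  rois <- build_candidate_mask(stk)
  expect_equal(rois$n_rois, 50)
  ids <- rois$label_image[cbind(round(sim$truth$row), round(sim$truth$col))]
  expect_true(all(ids > 0))
  expect_equal(length(unique(ids)), 50) # each center in its own ROI
})

test_that("a background-only stack yields an empty ROI set with a warning", {
  frames <- array(100, c(90, 64, 64))
  stack <- time_lapse_stack(frames, stack_timing())
  expect_warning(rois <- build_candidate_mask(stack), "empty ROI set")
  expect_equal(rois$n_rois, 0)
  expect_equal(nrow(rois$info), 0)
})

test_that("two boutons at the minimum separation are split by the watershed", {
  stack <- two_spot_stack(sep_px = 6, sigma = 1.5)
  rois <- build_candidate_mask(stack)
  expect_equal(rois$n_rois, 2)
  expect_gt(min(rois$info$area_px), 4)
})

test_that("roi labels are consecutive and disjoint with correct geometry", {
  sim <- simulate_experiment(sim_config(n_boutons = 20,
                                        image_shape = c(128, 128), seed = 22))
  stk <- subtract_stack_background(sim$stack)
  rois <- build_candidate_mask(stk)
  labs <- sort(unique(as.vector(rois$label_image)))
  expect_identical(labs, c(0L, seq_len(rois$n_rois)))
  expect_equal(sum(rois$info$area_px), sum(rois$label_image > 0))
  within_bounds <- rois$info$area_px >= 5 & rois$info$area_px <= 400
  expect_true(all(within_bounds))
})

test_that("per-ROI traces equal the brute-force pixel means", {
  sim <- simulate_experiment(sim_config(n_boutons = 10,
                                        image_shape = c(96, 96), seed = 23))
  stk <- subtract_stack_background(sim$stack)
  rois <- build_candidate_mask(stk)
  expect_gt(rois$n_rois, 0)
  fast <- roi_traces(stk, rois)
  slow <- oracle_roi_traces(stk, rois)
  expect_equal(unname(fast), slow, tolerance = 1e-9)
})

test_that("quality statistics are exact on a forced step trace", {
  lab <- matrix(0L, 16, 16)
  lab[4:6, 4:6] <- 1L
  tr <- matrix(c(rep(100, 30), rep(60, 60)), 1)
  stack <- stack_from_traces(lab, tr)
  v <- classify_roi_quality(stack, roi_set(lab))
  expect_equal(v$baseline_slope, 0)
  expect_equal(v$baseline_cv, 0)
  expect_equal(v$unloading_extent, 0.40)
  expect_true(v$passed)
  expect_equal(v$failure_reasons, "")
})

test_that("a flat trace fails on unloading extent only", {
  lab <- matrix(0L, 16, 16)
  lab[4:6, 4:6] <- 1L
  stack <- stack_from_traces(lab, matrix(rep(100, 90), 1))
  v <- classify_roi_quality(stack, roi_set(lab))
  expect_false(v$passed)
  expect_equal(v$failure_reasons, "extent")
  expect_equal(v$unloading_extent, 0)
})

test_that("a baseline ramp fails on slope, matching the closed form", {
  lab <- matrix(0L, 16, 16)
  lab[4:6, 4:6] <- 1L
  base <- seq(100, 130, length.out = 30)
  tr <- matrix(c(base, model_trace(130, 0.4, 4, 0, 60)), 1)
  stack <- stack_from_traces(lab, tr)
  v <- classify_roi_quality(stack, roi_set(lab))
  # least-squares slope of an arithmetic ramp equals its common difference
  expected_slope <- (30 / 29) / mean(base)
  expect_equal(v$baseline_slope, expected_slope, tolerance = 1e-12)
  expect_false(v$passed)
  expect_match(v$failure_reasons, "slope")
})

test_that("quality classification is invariant to intensity scaling", {
  sim <- simulate_experiment(sim_config(n_boutons = 10,
                                        image_shape = c(96, 96), seed = 24))
  stk <- subtract_stack_background(sim$stack)
  rois <- build_candidate_mask(stk)
  v1 <- classify_roi_quality(stk, rois)
  scaled <- time_lapse_stack(stk$frames * 7.3, stk$timing)
  v2 <- classify_roi_quality(scaled, rois)
  expect_equal(v1$baseline_slope, v2$baseline_slope, tolerance = 1e-9)
  expect_equal(v1$baseline_cv, v2$baseline_cv, tolerance = 1e-9)
  expect_equal(v1$unloading_extent, v2$unloading_extent, tolerance = 1e-9)
  expect_identical(v1$passed, v2$passed)
})

test_that("edge-ROI removal is the identity under a full valid mask", {
  lab <- matrix(0L, 32, 32)
  lab[3:5, 3:5] <- 1L
  lab[20:22, 20:22] <- 2L
  rois <- roi_set(lab)
  kept <- remove_edge_rois(rois, matrix(TRUE, 32, 32))
  expect_identical(kept$label_image, rois$label_image)
  expect_length(attr(kept, "removed_ids"), 0)
})

test_that("ROIs touching the invalid border strip are removed entirely", {
  lab <- matrix(0L, 32, 32)
  lab[1:3, 10:12] <- 1L    # touches the top border
  lab[15:17, 15:17] <- 2L  # interior
  lab[30:32, 2:4] <- 3L    # bottom-left corner
  valid <- matrix(TRUE, 32, 32)
  valid[1:3, ] <- FALSE   # as after a (3, -2) shift
  valid[, 1:2] <- FALSE
  kept <- remove_edge_rois(roi_set(lab), valid)
  expect_equal(kept$n_rois, 1)
  expect_equal(sort(attr(kept, "removed_ids")), c(1L, 3L))
  # the surviving ROI keeps its pixel set, relabeled to 1
  expect_identical(which(kept$label_image == 1L),
                   which(lab == 2L))
})
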