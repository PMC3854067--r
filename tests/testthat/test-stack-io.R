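test_that("stack write/read round-trips 16-bit integer data bit-exactly", {
  set.seed(1)
  frames <- array(sample(0:16383, 100 * 64 * 64, replace = TRUE),
                  c(100, 64, 64))
  stack <- time_lapse_stack(frames, stack_timing(30, 30, 10))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(stack, path)
  back <- read_stack(path, stack_timing(30, 30, 10))
  expect_identical(dim(back$frames), c(100L, 64L, 64L))
  expect_identical(back$frames, stack$frames)
  expect_equal(back$timing$stim_start_frame, 30L)
})

test_that("too few frames for the stimulation window is rejected", {
  frames <- array(10, c(20, 16, 16))
  expect_error(time_lapse_stack(frames, stack_timing(30, 30, 10)),
               "at least")
  # and via the reader
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(time_lapse_stack(array(5, c(35, 16, 16)),
                               stack_timing(15, 15, 10)), path)
  expect_error(read_stack(path, stack_timing(30, 30, 10)), "at least")
})

test_that("timing invariants are enforced", {
  expect_error(stack_timing(30, 20, 10), "stim_start_frame")
  expect_error(time_lapse_stack(array(-1, c(45, 8, 8)), stack_timing()),
               "negative")
  expect_error(time_lapse_stack(array(20000L, c(45, 8, 8)),
                                stack_timing(bit_depth = 14)),
               "bit_depth")
})

test_that("RGB / multi-sample TIFF is rejected with a clear message", {
  path <- withr::local_tempfile(fileext = ".tif")
  rgb <- array(runif(16 * 16 * 3), c(16, 16, 3))
  tiff::writeTIFF(rgb, path)
  expect_error(read_channel(path), "grayscale")
})

test_that("channel image round-trips and reports a full valid mask", {
  set.seed(2)
  px <- matrix(sample(0:4095, 64 * 64, replace = TRUE), 64, 64)
  ch <- channel_image(px, "marker_a")
  path <- withr::local_tempfile(fileext = ".tif")
  write_channel(ch, path)
  back <- read_channel(path, "marker_a")
  expect_equal(sum(back$valid_mask), 4096)
  expect_identical(back$pixels, ch$pixels)
  expect_equal(back$channel_name, "marker_a")
})

test_that("multi-frame TIFF is rejected by the channel reader", {
  path <- withr::local_tempfile(fileext = ".tif")
  stack <- time_lapse_stack(array(7, c(45, 8, 8)), stack_timing())
  write_stack(stack, path)
  expect_error(read_channel(path), "single-frame")
})

test_that("label masks round-trip", {
  lab <- matrix(0L, 32, 32)
  lab[3:5, 3:5] <- 1L
  lab[20:24, 10:12] <- 2L
  path <- withr::local_tempfile(fileext = ".tif")
  write_label_mask(lab, path)
  expect_identical(read_label_mask(path), lab)
})

test_that("write_results writes tables losslessly and lists them", {
  out_dir <- withr::local_tempdir()
  set.seed(3)
  roi_tab <- tibble::tibble(roi_id = 1:10, area_px = sample(5:40, 10),
                            norm_ir = rnorm(10), unloaded_pct = runif(10) * 50)
  manifest <- write_results(
    list(roi_table = roi_tab,
         group_summary = tibble::tibble(group = "whole", n = 10L),
         metadata = list(threshold_k = 4, note = "run")),
    out_dir)
  expect_equal(nrow(manifest), 3)
  expect_true(all(file.exists(manifest$file)))
  back <- readr::read_csv(manifest$file[manifest$type == "csv"][1],
                          show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(roi_tab))
})

test_that("an empty ROI table still yields a header-only CSV", {
  out_dir <- withr::local_tempdir()
  empty <- tibble::tibble(roi_id = integer(), norm_ir = double())
  manifest <- write_results(list(roi_table = empty), out_dir)
  lines <- readLines(manifest$file[1])
  expect_equal(lines, "roi_id,norm_ir")
})
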