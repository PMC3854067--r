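step_stack <- function(levels_before = 100, levels_after = 60) {
  lab <- matrix(0L, 16, 16)
  lab[4:6, 4:6] <- 1L
  tr <- matrix(c(rep(levels_before, 30), rep(levels_after, 60)), 1)
  list(stack = stack_from_traces(lab, tr), rois = roi_set(lab))
}

test_that("a clean step trace yields the forced unloaded fraction", {
  s <- step_stack(100, 60)
  rec <- compute_kinetics(s$stack, s$rois)
  expect_equal(rec$unloaded_fraction, 0.40)
  expect_equal(rec$unloaded_pct, 40)
  expect_equal(rec$f0, 100)
  s0 <- step_stack(80, 80)
  expect_equal(compute_kinetics(s0$stack, s0$rois)$unloaded_fraction, 0)
})

test_that("normalized traces average exactly one over the baseline", {
  sim <- simulate_experiment(sim_config(n_boutons = 10,
                                        image_shape = c(96, 96), seed = 51))
  stk <- subtract_stack_background(sim$stack)
  rois <- build_candidate_mask(stk)
  rec <- compute_kinetics(stk, rois)
  for (tr in rec$norm_trace) {
    expect_equal(mean(tr[1:30]), 1, tolerance = 1e-12)
  }
})

test_that("noise-free measured kinetics equal the analytic nominal value", {
  # isolated boutons: the closed form describes a single spot's trace, so
  # neighbour-tail crosstalk has to be negligible for 1e-6 agreement
  cfg <- sim_config(n_boutons = 15, image_shape = c(196, 196), noise_sd = 0,
                    background_level = 0, background_gradient = 0,
                    min_separation_factor = 16, seed = 52)
  sim <- simulate_experiment(cfg)
  rois <- build_candidate_mask(sim$stack)
  expect_equal(rois$n_rois, 15)
  rec <- compute_kinetics(sim$stack, rois)
  # match ROIs to planted boutons via the label under each truth center
  ids <- rois$label_image[cbind(round(sim$truth$row), round(sim$truth$col))]
  nominal <- vapply(sim$truth$unload_fraction, nominal_unloaded_fraction, 1,
                    tau_frames = cfg$unload_tau_frames,
                    stim_start = cfg$n_baseline_frames,
                    trace_end = cfg$n_frames, tail_window = 10)
  measured <- rec$unloaded_fraction[match(ids, rec$roi_id)]
  expect_equal(measured, nominal, tolerance = 1e-6)
})

test_that("identical group values give F = 0, p = 1, nothing significant", {
  lab <- matrix(0L, 24, 24)
  lab[cbind(rep(seq(2, 22, by = 4), each = 1), 3)] <- 0L # no-op, clarity
  k <- 0L
  for (r in seq(2, 21, by = 4)) for (c_ in seq(2, 21, by = 4)) {
    k <- k + 1L
    lab[r, c_] <- k
  }
  tr <- matrix(rep(c(rep(100, 30), rep(60, 60)), k), k, byrow = TRUE)
  stack <- stack_from_traces(lab, tr)
  rec <- compute_kinetics(stack, roi_set(lab))
  groups <- factor(rep(c("low", "mid", "high"), length.out = k),
                   levels = c("low", "mid", "high"))
  s <- summarize_groups(rec, groups)
  expect_equal(s$anova$f, 0)
  expect_equal(s$anova$p, 1)
  expect_false(any(s$pairwise$significant))
})

test_that("ANOVA and pairwise tests match textbook formulas on a fixed table", {
  # fixed fixture: three groups of five unloaded fractions
  vals <- c(0.31, 0.35, 0.33, 0.36, 0.30,
            0.41, 0.44, 0.39, 0.42, 0.45,
            0.25, 0.28, 0.24, 0.27, 0.26)
  grp <- rep(c("whole", "high", "low"), each = 5)
  lab <- matrix(0L, 40, 40)
  k <- 0L
  for (r in seq(2, 38, by = 7)) for (c_ in seq(2, 38, by = 7)) {
    if (k < 15) { k <- k + 1L; lab[r, c_] <- k }
  }
  tr <- t(vapply(vals, function(u) model_trace(100, u, 1e-9), numeric(90)))
  stack <- stack_from_traces(lab, tr)
  rec <- compute_kinetics(stack, roi_set(lab))
  expect_equal(rec$unloaded_fraction, vals, tolerance = 1e-9)
  groups <- factor(ifelse(grp == "whole", "mid", grp),
                   levels = c("low", "mid", "high"))
  s <- summarize_groups(rec, groups)
  # oracle operates on the same overlapping populations the summary uses
  whole_vals <- vals
  high_vals <- vals[groups == "high"]
  low_vals <- vals[groups == "low"]
  ov <- c(whole_vals, high_vals, low_vals)
  og <- rep(c("whole", "high", "low"), c(15, 5, 5))
  oracle <- oracle_anova(ov, og)
  expect_equal(s$anova$f, oracle$f, tolerance = 1e-9)
  expect_equal(s$anova$p, oracle$p, tolerance = 1e-9)
  # Bonferroni: three pairs, raw p multiplied by 3 and capped at 1
  expect_equal(nrow(s$pairwise), 3)
  expect_equal(s$pairwise$p_adj, pmin(1, s$pairwise$p_raw * 3))
})

test_that("with one subpopulation empty only one pair is tested, factor 1", {
  s <- step_stack()
  lab <- matrix(0L, 24, 24)
  for (k in 1:6) lab[4 * k - 2, 4] <- k
  set.seed(53)
  u <- runif(6, 0.3, 0.5)
  tr <- t(vapply(u, function(ui) model_trace(100, ui, 3), numeric(90)))
  stack <- stack_from_traces(lab, tr)
  rec <- compute_kinetics(stack, roi_set(lab))
  groups <- factor(c("high", "high", "high", "mid", "mid", "mid"),
                   levels = c("low", "mid", "high"))
  sm <- summarize_groups(rec, groups) # low is empty: pairs = whole vs high
  expect_equal(nrow(sm$pairwise), 1)
  expect_equal(sm$pairwise$p_adj, pmin(1, sm$pairwise$p_raw))
  expect_equal(sm$groups$n[sm$groups$group == "low"], 0)
})

test_that("an empty high and low population skips the ANOVA with a warning", {
  lab <- matrix(0L, 24, 24)
  for (k in 1:4) lab[4 * k, 4] <- k
  tr <- matrix(rep(c(rep(100, 30), rep(55, 60)), 4), 4, byrow = TRUE)
  stack <- stack_from_traces(lab, tr)
  rec <- compute_kinetics(stack, roi_set(lab))
  groups <- factor(rep("mid", 4), levels = c("low", "mid", "high"))
  expect_warning(sm <- summarize_groups(rec, groups), "ANOVA skipped")
  expect_null(sm$anova)
  expect_true(is.na(glance(sm)$p.value))
})

test_that("group traces carry mean, SEM and n per frame and start near one", {
  sim <- simulate_experiment(sim_config(n_boutons = 30, seed = 54))
  res <- quiet_pipeline(sim$stack,
                        list(marker_a = sim$marker_a, marker_b = sim$marker_b))
  tr <- res$summary$traces
  expect_true(all(c("group", "frame", "time_s", "mean", "sem", "n") %in%
                    names(tr)))
  whole <- dplyr::filter(tr, group == "whole")
  expect_equal(mean(whole$mean[1:30]), 1, tolerance = 1e-9)
  # SEM uses the n-1 sample standard deviation
  rec_mat <- do.call(rbind, res$kinetics$norm_trace)
  expect_equal(whole$sem[1],
               sd(rec_mat[, 1]) / sqrt(nrow(rec_mat)), tolerance = 1e-12)
})

test_that("the disjoint high/mid/low variant is reported alongside", {
  set.seed(55)
  lab <- matrix(0L, 40, 40)
  k <- 0L
  for (r in seq(2, 38, by = 5)) for (c_ in seq(2, 38, by = 5)) {
    if (k < 30) { k <- k + 1L; lab[r, c_] <- k }
  }
  u <- runif(30, 0.2, 0.6)
  tr <- t(vapply(u, function(ui) model_trace(100, ui, 4), numeric(90)))
  stack <- stack_from_traces(lab, tr)
  rec <- compute_kinetics(stack, roi_set(lab))
  groups <- factor(sample(c("low", "mid", "high"), 30, replace = TRUE),
                   levels = c("low", "mid", "high"))
  sm <- summarize_groups(rec, groups)
  expect_false(is.null(sm$disjoint))
  expect_setequal(sm$disjoint$groups$group, c("low", "mid", "high"))
  # n_whole >= n_high + n_low
  n <- setNames(sm$groups$n, sm$groups$group)
  expect_gte(n[["whole"]], n[["high"]] + n[["low"]])
})
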