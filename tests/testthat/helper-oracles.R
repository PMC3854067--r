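# Independent brute-force oracles and small fixture builders. Everything
# here is deliberately naive (double loops, textbook formulas) and shares no
# code with the implementation paths it checks.

# Grayscale opening with a non-flat ball structuring element, direct
# min/max double loop over the structuring element.
oracle_rolling_ball <- function(img, radius) {
  ri <- floor(radius)
  off <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  off$h <- sqrt(radius^2 - off$dr^2 - off$dc^2)
  nr <- nrow(img); nc <- ncol(img)
  ero <- matrix(NA_real_, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    rr <- r + off$dr; cc <- c + off$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    ero[r, c] <- min(img[cbind(rr[ok], cc[ok])] - off$h[ok])
  }
  bg <- matrix(NA_real_, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    rr <- r + off$dr; cc <- c + off$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    bg[r, c] <- max(ero[cbind(rr[ok], cc[ok])] + off$h[ok])
  }
  bg
}

# Textbook one-way ANOVA sums of squares.
oracle_anova <- function(values, groups) {
  groups <- factor(groups)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ssb <- sum(gn * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = pf(f, df1, df2, lower.tail = FALSE))
}

# Per-ROI per-frame mean by explicit loops.
oracle_roi_traces <- function(stack, rois) {
  nt <- dim(stack$frames)[1]
  out <- matrix(NA_real_, rois$n_rois, nt)
  for (k in seq_len(rois$n_rois)) {
    idx <- which(rois$label_image == k, arr.ind = TRUE)
    for (t in seq_len(nt)) {
      out[k, t] <- mean(stack$frames[t, , ][idx])
    }
  }
  out
}

# Build a stack whose ROI pixels carry prescribed traces on a flat
# background; label_image gives the ROI geometry.
stack_from_traces <- function(label_image, traces, background = 0,
                              timing = stack_timing()) {
  nt <- ncol(traces)
  nr <- nrow(label_image); nc <- ncol(label_image)
  frames <- array(background, c(nt, nr, nc))
  for (t in seq_len(nt)) {
    f <- frames[t, , ]
    for (k in seq_len(nrow(traces))) f[label_image == k] <- traces[k, t]
    frames[t, , ] <- f
  }
  time_lapse_stack(frames, timing)
}

# A 90-frame trace following the package's destaining model.
model_trace <- function(f0, u, tau, stim_start = 30, n = 90) {
  t0 <- seq_len(n) - 1
  dt <- t0 - stim_start
  decay <- ifelse(dt < 0, 1, exp(-pmax(dt, 0) / max(tau, 1e-12)))
  f0 * ((1 - u) + u * decay)
}

# Two Gaussian spots with destaining traces, rendered explicitly.
two_spot_stack <- function(sep_px, sigma = 1.5, f0 = c(2000, 1500),
                           u = c(0.4, 0.35), tau = 4, shape = c(64, 64)) {
  centers <- rbind(c(32, 32 - sep_px / 2), c(32, 32 + sep_px / 2))
  nt <- 90
  frames <- array(0, c(nt, shape[1], shape[2]))
  for (i in 1:2) {
    g <- exp(-outer((seq_len(shape[1]) - centers[i, 1])^2,
                    (seq_len(shape[2]) - centers[i, 2])^2, "+") /
               (2 * sigma^2))
    tr <- model_trace(f0[i], u[i], tau)
    for (t in seq_len(nt)) frames[t, , ] <- frames[t, , ] + tr[t] * g
  }
  time_lapse_stack(frames, stack_timing())
}

# Recall/precision of a segmentation against planted bouton centers:
# a bouton is recovered when its (rounded) center falls in some ROI, each
# ROI counts as correct when it is hit by at least one center.
seg_match_stats <- function(truth, rois) {
  ids <- rois$label_image[cbind(round(truth$row), round(truth$col))]
  hit <- unique(ids[ids > 0])
  c(recall = length(hit) / nrow(truth),
    precision = length(hit) / max(rois$n_rois, 1))
}

# Smooth random field for registration fixtures: sum of random Gaussians.
random_spot_field <- function(shape = c(96, 96), n_spots = 40, sigma = 2,
                              margin = 25) {
  img <- matrix(0, shape[1], shape[2])
  rs <- runif(n_spots, margin, shape[1] - margin)
  cs <- runif(n_spots, margin, shape[2] - margin)
  amp <- runif(n_spots, 50, 200)
  for (i in seq_len(n_spots)) {
    g <- exp(-outer((seq_len(shape[1]) - rs[i])^2,
                    (seq_len(shape[2]) - cs[i])^2, "+") / (2 * sigma^2))
    img <- img + amp[i] * g
  }
  img
}

# Integer-translate an image, zero-filling: out(r, c) = img(r - dr, c - dc).
translate_image <- function(img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  r_dst <- max(1, 1 + dr):min(nr, nr + dr)
  c_dst <- max(1, 1 + dc):min(nc, nc + dc)
  out[r_dst, c_dst] <- img[r_dst - dr, c_dst - dc]
  out
}

quiet_pipeline <- function(...) {
  suppressWarnings(run_pipeline(...))
}
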