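# Surrogate-signal extraction: steady state, edge tracking, body mask,
# reference frame, spline resampling, PCA.

test_that("pre-steady-state trimming removes exactly the inflated leading run", {
  img <- fixture_image(c(32, 32))
  frames <- array(rep(img, 12), dim = c(32, 32, 12))
  series <- cine_series(frames, 1:12, c(2, 2), "sagittal", "surrogate")
  out <- discard_pre_steady_state(series)
  expect_equal(out$n_discarded, 0L)
  # inflate the first 3 frames by +20%, threshold 0.05
  frames2 <- frames
  for (i in 1:3) frames2[, , i] <- frames2[, , i] * 1.2
  series2 <- cine_series(frames2, 1:12, c(2, 2), "sagittal", "surrogate")
  out2 <- discard_pre_steady_state(series2, 0.05)
  expect_equal(out2$n_discarded, 3L)
  expect_equal(out2$series$times_s, 4:12)
  # an inflated frame later in the series is never removed
  frames3 <- frames
  frames3[, , 7] <- frames3[, , 7] * 1.3
  out3 <- discard_pre_steady_state(
    cine_series(frames3, 1:12, c(2, 2), "sagittal", "surrogate"), 0.05)
  expect_equal(out3$n_discarded, 0L)
  # all frames above threshold: no steady state
  up <- array(rep(img, 4) * rep(c(8, 4, 2, 1.5), each = length(img)),
              dim = c(32, 32, 4))
  expect_error(discard_pre_steady_state(
    cine_series(up, 1:4, c(2, 2), "sagittal", "surrogate")), "steady state")
})

test_that("realistic synthetic acquisition discards a small leading run", {
  sim <- fixture_small_sim()
  out <- discard_pre_steady_state(sim$surrogate)
  expect_gte(out$n_discarded, 2)
  expect_lte(out$n_discarded, 5)
})

test_that("edge tracking recovers half-pixel steps within 0.1 px RMS", {
  fx <- fixture_edge_series(n_frames = 8, step_px = 0.5, axis = "SI")
  sig <- track_edge(fx$series, c(round(fx$positions[1]), 15), c(20, 10), axis = "SI")
  pos <- attr(sig, "positions_px")
  err <- (pos - mean(pos)) - (fx$positions - mean(fx$positions))
  expect_lt(sqrt(mean(err^2)), 0.1)
  # increments are 0.5 px within 0.1 px
  expect_lt(max(abs(diff(pos) - 0.5)), 0.1)
  # signal sign: edge moving to larger row (inferior) must be negative (inhale)
  expect_lt(sig$sample_values[8], sig$sample_values[1])
  # identical frames give a zero signal
  still <- fx$series
  for (t in 2:8) still$frames[, , t] <- still$frames[, , 1]
  s0 <- track_edge(still, c(round(fx$positions[1]), 15), c(20, 10), axis = "SI")
  expect_lt(max(abs(s0$sample_values)), 1e-9)
  # the relative-to-average definition makes the mean exactly zero
  expect_lt(abs(mean(sig$sample_values)), 1e-9)
})

test_that("AP tracking mirrors SI tracking and flags untrackable windows", {
  fx <- fixture_edge_series(n_frames = 6, step_px = 0.4, axis = "AP",
                            shape = c(30, 40))
  sig <- track_edge(fx$series, c(15, round(fx$positions[1])), c(6, 20), axis = "AP")
  pos <- attr(sig, "positions_px")
  expect_lt(max(abs(diff(pos) - 0.4)), 0.1)
  # posterior motion (larger col) is positive
  expect_gt(sig$sample_values[6], sig$sample_values[1])
  flat <- fx$series
  flat$frames[] <- 0.5
  expect_error(track_edge(flat, c(15, 20), c(6, 20), axis = "AP"), "frame 1")
  expect_error(track_edge(fx$series, c(2, 2), c(20, 10), axis = "SI"), "window")
})

test_that("diaphragm and skin signals track the known phantom motion", {
  sim <- fixture_small_sim()
  surr <- discard_pre_steady_state(sim$surrogate)$series
  ph <- sim$phantom
  dia <- diaphragm_signal(surr, ph$diaphragm_seed_point)
  # oracle: ground-truth DVF at the diaphragm point
  gt <- sim$ground_truth
  shape <- dim(ph$reference_image)
  B <- bspline_matrix(gt$grid_template, shape, ph$pixel_spacing_mm)
  true_si <- vapply(surr$times_s, function(t) {
    u <- compose_sliding_dvf(gt_transform_at(gt, t), shape, ph$pixel_spacing_mm, B = B)
    u$displacements[ph$diaphragm_seed_point[1], ph$diaphragm_seed_point[2], 1]
  }, 0)
  truth <- -(true_si - mean(true_si))
  expect_gt(cor(dia$sample_values, truth), 0.99)
  expect_lt(abs(diff(range(dia$sample_values)) - diff(range(truth))) /
              diff(range(truth)), 0.1)
  # the skin surrogate is deliberately noisy (soft boundary, 3 mm excursion)
  # but must still track the true chest-wall AP motion
  skin <- skin_signal(surr, ph$skin_seed_point)
  true_ap <- vapply(surr$times_s, function(t) {
    u <- compose_sliding_dvf(gt_transform_at(gt, t), shape, ph$pixel_spacing_mm, B = B)
    u$displacements[ph$skin_seed_point[1], ph$skin_seed_point[2], 2]
  }, 0)
  expect_gt(cor(skin$sample_values, true_ap - mean(true_ap)), 0.5)
})

test_that("signals are invariant to intensity offsets and equivariant to shifts", {
  fx <- fixture_edge_series(n_frames = 6, step_px = 0.3)
  seed <- c(round(fx$positions[1]), 15)
  base <- track_edge(fx$series, seed, c(20, 10), axis = "SI")
  shifted <- fx$series
  shifted$frames <- shifted$frames + 5
  s2 <- track_edge(shifted, seed, c(20, 10), axis = "SI")
  expect_lt(max(abs(s2$sample_values - base$sample_values)), 1e-9)
  # whole-series spatial translation moves the tracked positions equally
  trans <- fx$series
  trans$frames <- trans$frames[c(3:dim(trans$frames)[1], 1, 1), , , drop = FALSE]
  s3 <- track_edge(trans, seed - c(2, 0), c(20, 10), axis = "SI")
  p_base <- attr(base, "positions_px"); p_tr <- attr(s3, "positions_px")
  expect_lt(max(abs((p_base - p_tr) - 2)), 0.05)
})

test_that("body mask covers the phantom body and honours the closing radius", {
  sim <- fixture_small_sim()
  ref <- sim$surrogate$frames[, , 10]
  mask <- make_body_mask(ref)
  ph <- sim$phantom
  eroded <- EBImage::erode(ph$body_mask, EBImage::makeBrush(9, "disc"))
  expect_gt(mean(mask[eroded > 0]), 0.98)          # body interior included
  corners <- mask[c(1, 64), c(1, 64)]
  expect_true(all(corners == 0))                    # background excluded
  # without closing the dark lung is excluded; with it, included
  m0 <- make_body_mask(ref, closing_radius_px = 0)
  lung <- ph$region_mask == 1 & ph$reference_image < 0.2
  expect_lt(mean(m0[lung]), 0.5)
  expect_gt(mean(mask[lung]), 0.9)
  expect_error(make_body_mask(matrix(1, 16, 16)), "constant")
})

test_that("reference frame selection: ramp, tie-break and sinusoid cases", {
  mk <- function(positions) {
    shape <- c(40, 24)
    frames <- array(0, dim = c(shape, length(positions)))
    rr <- matrix(rep(seq_len(shape[1]), shape[2]), shape[1])
    for (t in seq_along(positions)) {
      frames[, , t] <- 1 / (1 + exp(-(rr - positions[t]) / 0.8))
    }
    cine_series(frames, seq_along(positions), c(2, 2), "sagittal", "surrogate")
  }
  # linear drift: mean position is at the middle
  drift <- mk(15 + 0.2 * (0:19))
  expect_warning(i <- select_reference_frame(drift, c(17, 12), k = 30), "frames")
  expect_lte(abs(i - 10.5), 1.5)
  # constant: earliest index wins
  const <- mk(rep(18, 10))
  expect_warning(i0 <- select_reference_frame(const, c(18, 12), k = 30))
  expect_equal(i0, 1L)
  # whole sinusoid cycles: returned frame near mid-position (oracle: argmin)
  pos <- 18 + 4 * sin(2 * pi * (0:29) / 10)
  sine <- mk(pos)
  i2 <- select_reference_frame(sine, c(18, 12), k = 30)
  expect_equal(i2, which.min(abs(pos - mean(pos))))
  expect_lt(abs(pos[i2] - mean(pos)), 0.05 * 8)
})

test_that("intensity PCA matches a brute-force eigendecomposition", {
  set.seed(2)
  frames <- array(rnorm(10 * 10 * 6), dim = c(10, 10, 6))
  series <- cine_series(frames, 1:6, c(1, 1), "sagittal", "surrogate")
  p <- pca_intensity(series, n_components = 3)
  # oracle: eigendecomposition of the covariance of centred data
  X <- t(matrix(frames, 100, 6))
  Xc <- sweep(X, 2, colMeans(X))
  eg <- eigen(Xc %*% t(Xc))                 # frame-space covariance (n < p)
  for (k in 1:3) {
    sc_o <- eg$vectors[, k] * sqrt(eg$values[k])
    sc <- p$component_scores[, k]
    expect_lt(min(max(abs(sc - sc_o)), max(abs(sc + sc_o))), 1e-8)
  }
  expect_lt(abs(sum(p$all_explained_variance) - 1), 1e-9)
  expect_true(all(diff(p$explained_variance_fraction) <= 1e-12))
  expect_lt(max(abs(colMeans(p$component_scores))), 1e-8)
  # orthogonality of scores
  g <- crossprod(p$component_scores)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)
})

test_that("rank-1 series loads entirely on PC1 with the pattern as its map", {
  img <- fixture_image(c(12, 12))
  pattern <- matrix(sin(seq_len(144) / 7), 12, 12)
  alpha <- c(0.3, -1, 0.5, 2, -0.7, 1.4)
  frames <- array(0, dim = c(12, 12, 6))
  for (t in 1:6) frames[, , t] <- img + alpha[t] * pattern
  p <- pca_intensity(cine_series(frames, 1:6, c(1, 1), "sagittal", "surrogate"), 2)
  expect_gt(p$explained_variance_fraction[1], 0.999)
  m <- as.vector(p$coefficient_maps[[1]]); v <- as.vector(pattern) / sqrt(sum(pattern^2))
  expect_lt(min(max(abs(m - v)), max(abs(m + v))), 1e-8)
})

test_that("CPD PCA excludes out-of-body points and matches the eigensolve", {
  shape <- c(24, 24); h <- c(2, 2)
  body <- matrix(0, 24, 24); body[5:20, 5:20] <- 1
  set.seed(3)
  grids <- lapply(1:6, function(t) fixture_grid(shape, h, 10, amp = 3, seed = t))
  p <- pca_cpd(grids, body, h, n_components = 2, times_s = 1:6)
  keep <- p$retained_points
  # oracle eigensolve on the same retained components
  X <- t(vapply(grids, function(g) c(g$displacements[, , 1][keep],
                                     g$displacements[, , 2][keep]),
                numeric(2 * sum(keep))))
  Xc <- sweep(X, 2, colMeans(X))
  eg <- eigen(Xc %*% t(Xc))
  for (k in 1:2) {
    sc_o <- eg$vectors[, k] * sqrt(eg$values[k])
    expect_lt(min(max(abs(p$component_scores[, k] - sc_o)),
                  max(abs(p$component_scores[, k] + sc_o))), 1e-8)
  }
  # rank-2 CPD series concentrates on two components
  m1 <- fixture_grid(shape, h, 10, amp = 2, seed = 21)
  m2 <- fixture_grid(shape, h, 10, amp = 2, seed = 22)
  a <- sin(1:7); b <- cos(1:7)
  lin <- lapply(1:7, function(t) {
    g <- m1; g$displacements <- m1$displacements * a[t] + m2$displacements * b[t]
    g
  })
  p2 <- pca_cpd(lin, body, h, n_components = 3, times_s = 1:7)
  expect_gt(sum(p2$explained_variance_fraction[1:2]), 0.999)
  # zero motion gives all-zero scores
  zeros <- lapply(1:5, function(t) control_point_grid(shape, h, 10))
  p0 <- pca_cpd(zeros, body, h, n_components = 2, times_s = 1:5)
  expect_lt(max(abs(p0$component_scores)), 1e-12)
})

test_that("spline resampling: interpolation, polynomial fidelity, rejection", {
  tt <- seq(0, 10, by = 0.5)
  y <- 0.3 * tt^3 - 2 * tt^2 + tt - 5
  sig <- surrogate_signal("poly", tt, y, units = "a.u.")
  out <- resample_signal(sig, tt, smoothing_level = 0)
  expect_lt(max(abs(out$sample_values - y)), 1e-9)
  mid <- tt[-1] - 0.25
  out2 <- resample_signal(sig, mid, smoothing_level = 0)
  truth <- 0.3 * mid^3 - 2 * mid^2 + mid - 5
  expect_lt(max(abs(out2$sample_values - truth)[mid > 1 & mid < 9]), 1e-6)
  # out-of-span target times are rejected with their indices, never clipped
  out3 <- resample_signal(sig, c(-0.5, 3, 11))
  expect_equal(attr(out3, "rejected_indices"), c(1L, 3L))
  expect_equal(out3$sample_times_s, 3)
})

test_that("spline derivative matches the closed form for a sine", {
  f <- 0.25
  tt <- seq(0, 12, by = 0.1)
  sig <- surrogate_signal("sine", tt, sin(2 * pi * f * tt))
  res <- resample_signal(sig, tt)
  d <- derivative_signal(res)
  expect_match(d$name, "_deriv$")
  truth <- 2 * pi * f * cos(2 * pi * f * tt)
  sel <- tt > 1 & tt < 11
  expect_lt(sqrt(mean((d$sample_values - truth)[sel]^2)) / (2 * pi * f), 0.02)
  # derivative of a cosine is uncorrelated with it over whole cycles
  cy <- tt <= 8
  expect_lt(abs(cor(d$sample_values[cy], res$sample_values[cy])), 0.05)
  # constant signal: zero derivative
  cs <- resample_signal(surrogate_signal("c", tt, rep(2, length(tt))), tt)
  expect_lt(max(abs(derivative_signal(cs)$sample_values)), 1e-9)
})
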