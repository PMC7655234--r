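# Synthetic cine-MR generator: phantom, breathing trace, ground truth,
# rendering.

test_that("phantom masks nest correctly and geometry matches the config", {
  ph <- make_phantom()
  expect_true(all(ph$tumour_mask <= ph$region_mask))
  expect_true(all(ph$region_mask <= ph$body_mask))
  expect_true(all(ph$evaluation_mask <= ph$body_mask))
  expect_equal(dim(ph$region_mask), dim(ph$reference_image))
  # 1.98 mm spacing -> physical extent 1.98 * (shape - 1) mm per axis
  expect_equal((dim(ph$reference_image) - 1) * ph$pixel_spacing_mm,
               c(251.46, 251.46))
  # the diaphragm seed sits on a strong SI edge: >= 50% of the dynamic
  # range crossed within 3 pixels
  p <- ph$diaphragm_seed_point
  prof <- ph$reference_image[(p[1] - 3):(p[1] + 3), p[2]]
  expect_gte(diff(range(prof)), 0.5 * diff(range(ph$reference_image)))
  # skin seed on a strong AP edge
  s <- ph$skin_seed_point
  sprof <- ph$reference_image[s[1], (s[2] - 3):(s[2] + 3)]
  expect_gte(diff(range(sprof)), 0.5 * diff(range(ph$reference_image)))
})

test_that("degenerate and invalid phantom configurations", {
  cfg <- phantom_config(tumour_radius_mm = 0)
  ph <- make_phantom(cfg)
  expect_equal(sum(ph$tumour_mask), 0)
  expect_true(all(ph$region_mask <= ph$body_mask))
  expect_error(make_phantom(phantom_config(shape = c(32, 32))), "64")
  expect_error(make_phantom(phantom_config(pixel_spacing_mm = c(0, 1))), "positive")
})

test_that("zero-variability breathing is exactly periodic and seeded runs repeat", {
  tr <- generate_breathing(duration_s = 30, amplitude_sd = 0, period_sd = 0,
                           baseline_sd = 0, seed = 1)
  per <- tr$cycle_params$period[1]
  i <- which(tr$times_s >= per)[1]
  n <- length(tr$primary)
  expect_lt(max(abs(tr$primary[1:(n - i + 1)] - tr$primary[i:n])), 1e-9)
  tr2 <- generate_breathing(duration_s = 30, amplitude_sd = 0, period_sd = 0,
                            baseline_sd = 0, seed = 1)
  expect_identical(tr, tr2)
  trs <- generate_breathing(seed = 1)
  trs2 <- generate_breathing(seed = 1)
  expect_identical(trs, trs2)
  expect_false(identical(trs$primary, generate_breathing(seed = 2)$primary))
})

test_that("per-cycle peak amplitudes reflect the configured spread", {
  spread <- 0.15
  tr <- generate_breathing(duration_s = 85, period_s = 4, period_sd = 0,
                           amplitude_sd = spread, baseline_sd = 0, seed = 9)
  expect_gte(nrow(tr$cycle_params), 20)
  # oracle: the drawn per-cycle amplitudes themselves
  drawn_sd <- sd(tr$cycle_params$amplitude)
  expect_lt(abs(drawn_sd - spread) / spread, 0.5)
  # waveform peaks per cycle match the drawn amplitude + baseline
  cp <- tr$cycle_params
  ks <- which(cp$t_start + cp$period <= max(tr$times_s))
  peaks <- vapply(ks, function(k) {
    sel <- tr$times_s >= cp$t_start[k] & tr$times_s < cp$t_start[k] + cp$period[k]
    max(tr$primary[sel])
  }, 0)
  expect_lt(max(abs(peaks - (cp$amplitude + cp$baseline)[ks])), 0.02)
})

test_that("breath-hold freezes the primary signal and is validated", {
  tr <- generate_breathing(duration_s = 40, breath_hold = list(start_s = 20,
                                                               duration_s = 6),
                           seed = 3)
  sel <- tr$times_s >= 20 & tr$times_s <= 26
  expect_lt(diff(range(tr$primary[sel])), 1e-12)
  expect_lt(diff(range(tr$secondary[sel])), 1e-12)
  expect_error(generate_breathing(duration_s = 30,
                                  breath_hold = list(start_s = 28, duration_s = 5)),
               "outside")
})

test_that("hysteresis loop area is nonzero iff the phase lead is nonzero", {
  loop_area <- function(p, q) {
    n <- length(p)
    abs(sum(p * c(q[-1], q[1]) - c(p[-1], p[1]) * q)) / 2
  }
  tr <- generate_breathing(duration_s = 4, sample_rate_hz = 100, period_s = 4,
                           amplitude_sd = 0, period_sd = 0, baseline_sd = 0,
                           seed = 1)
  one <- tr$times_s < tr$cycle_params$period[1]
  expect_gt(loop_area(tr$primary[one], tr$secondary[one]), 0.01)
  tr0 <- generate_breathing(duration_s = 4, sample_rate_hz = 100, period_s = 4,
                            amplitude_sd = 0, period_sd = 0, baseline_sd = 0,
                            phase_lead = 0, seed = 1)
  expect_lt(loop_area(tr0$primary[one], tr0$secondary[one]), 1e-9)
})

test_that("ground truth is exactly linear in the latents with a zero reference", {
  sim <- fixture_small_sim()
  gt <- sim$ground_truth
  for (i in c(1, 5, 20)) {
    ev <- eval_breathing(gt$trace, gt$times_s[i])
    for (r in 1:2) {
      cf <- gt$coefficients[[r]]
      expected <- cf$c1 * ev$primary + cf$c2 * ev$secondary + cf$c0
      expect_lt(max(abs(gt$transforms[[i]]$region_grids[[r]]$displacements - expected)),
                1e-12)
    }
  }
  expect_equal(max(abs(flatten_cpd(gt$transforms[[gt$reference_index]]))), 0)
})

test_that("zero coefficient patterns give identity transforms everywhere", {
  ph <- make_phantom(phantom_config(shape = c(64L, 64L)))
  tr <- generate_breathing(duration_s = 10, seed = 1)
  gt <- generate_ground_truth(ph, tr, c(1, 3, 5),
                              coeff_spec = coeff_spec_default(0, 0, 0))
  u <- compose_sliding_dvf(gt$transforms[[2]], dim(ph$reference_image),
                           ph$pixel_spacing_mm)
  expect_equal(max(abs(u$displacements)), 0)
})

test_that("diaphragm control-point excursion matches the configured amplitude", {
  sim <- fixture_small_sim()
  gt <- sim$ground_truth
  ph <- sim$phantom
  tmpl <- gt$grid_template
  pr <- tmpl$origin_mm[1] + (seq_len(tmpl$grid_shape[1]) - 1) * tmpl$spacing_mm[1]
  pc <- tmpl$origin_mm[2] + (seq_len(tmpl$grid_shape[2]) - 1) * tmpl$spacing_mm[2]
  dia_mm <- (ph$diaphragm_seed_point - 1) * ph$pixel_spacing_mm
  ir <- which.min(abs(pr - dia_mm[1])); ic <- which.min(abs(pc - dia_mm[2]))
  # oracle: the linear formula at the trace extremes
  ev <- eval_breathing(gt$trace, seq(min(gt$times_s), max(gt$times_s), length.out = 2000))
  cf <- gt$coefficients[[2]]
  si <- cf$c1[ir, ic, 1] * ev$primary + cf$c2[ir, ic, 1] * ev$secondary
  expect_lt(abs(diff(range(si)) - 15) / 15, 0.1)
})

test_that("ground-truth motion slides across the region boundary", {
  sim <- fixture_small_sim()
  gt <- sim$ground_truth
  shape <- dim(sim$phantom$reference_image)
  # deepest-inhale frame: largest |primary - reference primary|
  ev <- eval_breathing(gt$trace, gt$times_s)
  i <- which.max(abs(ev$primary - ev$primary[gt$reference_index]))
  u <- compose_sliding_dvf(gt$transforms[[i]], shape, sim$phantom$pixel_spacing_mm)
  seg <- gt$segmentation
  edges <- which(seg[, -1] != seg[, -ncol(seg)], arr.ind = TRUE)
  jumps <- abs(u$displacements[, , 1][edges] -
                 u$displacements[, , 1][cbind(edges[, 1], edges[, 2] + 1)])
  expect_gt(max(jumps), 1)   # discontinuity across the sliding interface (mm)
})

test_that("rendering: zero motion is exact, frame counts and inflation behave", {
  ph <- make_phantom(phantom_config(shape = c(64L, 64L)))
  tr <- generate_breathing(duration_s = 6, seed = 1)
  gt0 <- generate_ground_truth(ph, tr, acquisition_times(
    acquisition_config(duration_s = 6, frame_rate_hz = 1))$motion,
    coeff_spec = coeff_spec_default(0, 0, 0))
  out <- render_series(ph, gt0, acquisition_config(duration_s = 6, frame_rate_hz = 1,
                                                   noise_sd_frac = 0,
                                                   steady_state_inflation = numeric(0)))
  for (i in seq_len(dim(out$motion$frames)[3])) {
    expect_equal(out$motion$frames[, , i], ph$reference_image, tolerance = 1e-12)
  }
  # ~1.9 fps for 60 s gives floor(60 * 1.9) +/- 1 motion frames
  n <- length(acquisition_times(acquisition_config(duration_s = 60,
                                                   frame_rate_hz = 1.9))$motion)
  expect_lte(abs(n - floor(60 * 1.9)), 1)
  # steady-state inflation raises the first frame's mean intensity
  sim <- fixture_small_sim()
  means <- apply(sim$surrogate$frames, 3, mean)
  expect_gt(means[1] / median(means), 1.2)
})

test_that("the simulated dataset is bit-reproducible from its seed", {
  a <- simulate_dataset(seed = 7, phantom_cfg = phantom_config(shape = c(64L, 64L)),
                        acquisition = acquisition_config(duration_s = 5))
  b <- simulate_dataset(seed = 7, phantom_cfg = phantom_config(shape = c(64L, 64L)),
                        acquisition = acquisition_config(duration_s = 5))
  expect_identical(a$surrogate$frames, b$surrogate$frames)
  expect_identical(a$motion$frames, b$motion$frames)
  expect_identical(a$trace, b$trace)
})

test_that("noise-free CPD trajectories are exactly recoverable by OLS", {
  sim <- fixture_small_sim()
  gt <- sim$ground_truth
  ev <- eval_breathing(gt$trace, gt$times_s)
  X <- cbind(ev$primary, ev$secondary, 1)
  Y <- t(vapply(gt$transforms, flatten_cpd,
                numeric(length(flatten_cpd(gt$transforms[[1]])))))
  beta <- qr.solve(X, Y)
  expect_lt(max(abs(X %*% beta - Y)), 1e-9)
})
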