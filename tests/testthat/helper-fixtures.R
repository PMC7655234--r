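# Small in-code fixtures shared across test files.

# A structured, non-constant test image (deterministic): a smooth random
# field, so every neighbourhood is a unique landmark (no periodic aliasing
# in registration tests).
fixture_image <- function(shape = c(48, 40), sigma = 2, seed = 123) {
  op <- function(n) {
    g <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * sigma^2))
    g / rowSums(g)
  }
  set.seed(seed)
  x <- op(shape[1]) %*% matrix(rnorm(prod(shape)), shape[1]) %*% t(op(shape[2]))
  (x - min(x)) / diff(range(x))
}

# A grid with pseudo-random displacements bounded by `amp` mm.
fixture_grid <- function(shape, h, cp_spacing, amp = 3, seed = 7) {
  g <- control_point_grid(shape, h, cp_spacing)
  set.seed(seed)
  g$displacements[, , 1] <- matrix(rnorm(prod(g$grid_shape), 0, amp / 2), g$grid_shape[1])
  g$displacements[, , 2] <- matrix(rnorm(prod(g$grid_shape), 0, amp / 2), g$grid_shape[1])
  g$displacements <- g$displacements * (amp / max(abs(g$displacements)))
  g
}

# Small cine series translating a soft step edge by `step_px` per frame
# along the given axis (sub-pixel tracking fixture). Returns the series and
# the true edge positions.
fixture_edge_series <- function(n_frames = 8, step_px = 0.5, axis = "SI",
                                shape = c(40, 30), edge0 = 17.3) {
  frames <- array(0, dim = c(shape, n_frames))
  pos <- edge0 + (seq_len(n_frames) - 1) * step_px
  coord <- if (axis == "SI") {
    matrix(rep(seq_len(shape[1]), times = shape[2]), shape[1])
  } else {
    matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1])
  }
  for (t in seq_len(n_frames)) {
    # smooth logistic edge: low above/left of the edge, high below/right
    frames[, , t] <- 1 / (1 + exp(-(coord - pos[t]) / 0.8))
  }
  list(series = cine_series(frames, seq_len(n_frames), c(1.98, 1.98),
                            "sagittal", "surrogate"),
       positions = pos)
}

# A tiny complete simulated dataset (64 x 64, ~25 s) for fast integration
# tests. Cached per session.
fixture_small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(
        seed = 42,
        phantom_cfg = phantom_config(shape = c(64L, 64L)),
        acquisition = acquisition_config(duration_s = 25, frame_rate_hz = 2))
    }
    cache
  }
})

# Deterministic list of sliding transforms linear in two latent signals,
# on a small geometry; used by model/evaluation tests without rendering.
fixture_linear_motion <- function(n_times = 12, shape = c(32, 32), h = c(2, 2),
                                  cp_spacing = 12, seed = 5) {
  set.seed(seed)
  template <- control_point_grid(shape, h, cp_spacing)
  gs <- template$grid_shape
  seg <- matrix(0, shape[1], shape[2]); seg[8:28, 10:28] <- 1
  mk <- function() array(rnorm(prod(gs) * 2, 0, 2), dim = c(gs, 2))
  coeff <- list(list(c0 = mk() * 0.1, c1 = mk(), c2 = mk()),
                list(c0 = mk() * 0.1, c1 = mk(), c2 = mk()))
  s1 <- sin(seq(0, 3 * pi, length.out = n_times))
  s2 <- cos(seq(0, 3 * pi, length.out = n_times)) * 0.5
  transforms <- lapply(seq_len(n_times), function(t) {
    grids <- lapply(coeff, function(cf) {
      g <- template
      g$displacements <- cf$c0 + cf$c1 * s1[t] + cf$c2 * s2[t]
      g
    })
    sliding_transform(grids, seg)
  })
  list(transforms = transforms, s1 = s1, s2 = s2, coeff = coeff,
       template = transforms[[1]], shape = shape, h = h, seg = seg)
}
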