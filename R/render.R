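# Rendering of interleaved surrogate / motion cine series from a phantom and
# ground-truth motion.

#' Cine series container
#'
#' @param frames Array `(rows, cols, n_frames)`.
#' @param times_s Strictly increasing frame times (s).
#' @param pixel_spacing_mm Per-axis spacing (mm).
#' @param orientation "sagittal" or "coronal".
#' @param role "surrogate" or "motion".
#' @export
cine_series <- function(frames, times_s, pixel_spacing_mm,
                        orientation = c("sagittal", "coronal"),
                        role = c("surrogate", "motion")) {
  orientation <- match.arg(orientation)
  role <- match.arg(role)
  if (dim(frames)[3] != length(times_s)) {
    stop("one timestamp per frame required", call. = FALSE)
  }
  if (any(diff(times_s) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  structure(list(frames = frames, times_s = as.numeric(times_s),
                 pixel_spacing_mm = rep(as.numeric(pixel_spacing_mm), length.out = 2),
                 orientation = orientation, role = role),
            class = "cine_series")
}

#' @export
print.cine_series <- function(x, ...) {
  cat(sprintf("<cine_series %s/%s> %d frames of %d x %d px (%.3g x %.3g mm), %.1f-%.1f s\n",
              x$orientation, x$role, dim(x$frames)[3], dim(x$frames)[1],
              dim(x$frames)[2], x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              min(x$times_s), max(x$times_s)))
  invisible(x)
}

#' Acquisition configuration for the synthetic scanner
#'
#' Emulates interleaved acquisition of a surrogate slice and a motion slice
#' from two fixed locations: each series runs at `frame_rate_hz`, with the
#' motion frames offset by half the frame interval.
#'
#' @param frame_rate_hz Per-series frame rate (default 1.9, the sagittal
#'   acquisition rate).
#' @param duration_s Acquisition duration (default 63 s, about one minute).
#' @param noise_sd_frac Additive Gaussian noise SD as a fraction of the
#'   reference dynamic range (default 0.02).
#' @param steady_state_inflation Multiplicative intensity factors applied to
#'   the leading surrogate frames, emulating acquisition before the
#'   longitudinal-magnetization steady state; `numeric(0)` disables it.
#' @param motion_orientation Orientation label of the motion series.
#' @export
acquisition_config <- function(frame_rate_hz = 1.9, duration_s = 63,
                               noise_sd_frac = 0.02,
                               steady_state_inflation = c(1.30, 1.18, 1.09),
                               motion_orientation = "sagittal") {
  if (noise_sd_frac < 0) stop("noise level must be non-negative", call. = FALSE)
  list(frame_rate_hz = frame_rate_hz, duration_s = duration_s,
       noise_sd_frac = noise_sd_frac,
       steady_state_inflation = steady_state_inflation,
       motion_orientation = motion_orientation)
}

#' Frame times of an acquisition (surrogate and motion interleaved)
#' @param acquisition From [acquisition_config()].
#' @return List with `surrogate` and `motion` time vectors (s).
#' @export
acquisition_times <- function(acquisition) {
  dt <- 1 / acquisition$frame_rate_hz
  n <- floor(acquisition$duration_s * acquisition$frame_rate_hz)
  surr <- (seq_len(n) - 1) * dt
  list(surrogate = surr, motion = surr + dt / 2)
}

#' Render interleaved surrogate and motion cine series
#'
#' Each frame is the phantom reference resampled through the ground-truth
#' transform at the frame time: the forward displacement field is inverted by
#' fixed-point iteration and the reference intensities are pulled back
#' through it, then Gaussian noise is added. Leading surrogate frames can be
#' intensity-inflated to emulate pre-steady-state acquisition.
#'
#' @param phantom A `phantom_anatomy`.
#' @param ground_truth A `ground_truth` generated at the motion times of
#'   `acquisition`.
#' @param acquisition From [acquisition_config()].
#' @param seed Integer seed for the noise.
#' @return List with `surrogate` and `motion` `cine_series`.
#' @export
render_series <- function(phantom, ground_truth, acquisition = acquisition_config(),
                          seed = 1) {
  times <- acquisition_times(acquisition)
  if (length(intersect(times$surrogate, times$motion))) {
    stop("surrogate and motion timestamps must interleave, not coincide", call. = FALSE)
  }
  shape <- dim(phantom$reference_image)
  h <- phantom$pixel_spacing_mm
  B <- bspline_matrix(ground_truth$grid_template, shape, h)
  drange <- diff(range(phantom$reference_image))

  # The ground truth is linear in (primary, secondary), so the composed
  # pixel field is too: precompute the two unit fields once.
  gt <- ground_truth
  ev0 <- eval_breathing(gt$trace, gt$times_s[gt$reference_index])
  field_for <- function(p, q) {
    grids <- lapply(gt$coefficients, function(cf) {
      g <- gt$grid_template
      g$displacements <- cf$c1 * p + cf$c2 * q + cf$c0
      g
    })
    compose_sliding_dvf(sliding_transform(grids, gt$segmentation), shape, h, B = B)
  }
  U1 <- field_for(ev0$primary + 1, ev0$secondary)$displacements
  U2 <- field_for(ev0$primary, ev0$secondary + 1)$displacements

  prev_inv <- NULL
  render_at <- function(t) {
    ev <- eval_breathing(gt$trace, t)
    u <- dvf(U1 * (ev$primary - ev0$primary) + U2 * (ev$secondary - ev0$secondary), h)
    if (max(abs(u$displacements)) < 1e-12) return(phantom$reference_image)
    v <- invert_dvf(u, init = prev_inv)
    prev_inv <<- v
    warp_image(phantom$reference_image, v)
  }
  n_s <- length(times$surrogate); n_m <- length(times$motion)
  surr <- array(0, dim = c(shape, n_s))
  mot <- array(0, dim = c(shape, n_m))
  # render in acquisition (time) order so the inversion warm start tracks
  all_t <- rbind(data.frame(t = times$surrogate, role = "s", idx = seq_len(n_s)),
                 data.frame(t = times$motion, role = "m", idx = seq_len(n_m)))
  all_t <- all_t[order(all_t$t), ]
  for (k in seq_len(nrow(all_t))) {
    fr <- render_at(all_t$t[k])
    if (all_t$role[k] == "s") surr[, , all_t$idx[k]] <- fr
    else mot[, , all_t$idx[k]] <- fr
  }

  infl <- acquisition$steady_state_inflation
  for (i in seq_along(infl)) if (i <= n_s) surr[, , i] <- surr[, , i] * infl[i]

  if (acquisition$noise_sd_frac > 0) {
    sd <- acquisition$noise_sd_frac * drange
    noise <- with_seed(seed, stats::rnorm(length(surr) + length(mot), 0, sd))
    surr <- surr + array(noise[seq_along(surr)], dim = dim(surr))
    mot <- mot + array(noise[length(surr) + seq_along(mot)], dim = dim(mot))
  }
  list(surrogate = cine_series(surr, times$surrogate, h, "sagittal", "surrogate"),
       motion = cine_series(mot, times$motion, h,
                            acquisition$motion_orientation, "motion"))
}

#' Simulate a complete synthetic cine-MR dataset
#'
#' Convenience driver: phantom, breathing trace, ground truth at the motion
#' times, and rendered interleaved series, all from one seed.
#'
#' @param seed Integer seed driving the trace and the rendering noise.
#' @param phantom_cfg,acquisition Configuration lists.
#' @param breathing Named list of overrides passed to [generate_breathing()].
#' @param cp_spacing_mm,coeff_spec Ground-truth motion parameterization.
#' @return List with `phantom`, `trace`, `ground_truth`, `surrogate`,
#'   `motion` and the configurations.
#' @export
simulate_dataset <- function(seed = 1, phantom_cfg = phantom_config(),
                             acquisition = acquisition_config(),
                             breathing = list(), cp_spacing_mm = 10,
                             coeff_spec = coeff_spec_default()) {
  phantom <- make_phantom(phantom_cfg)
  breathing$duration_s <- breathing$duration_s %||% acquisition$duration_s
  breathing$seed <- breathing$seed %||% seed
  trace <- do.call(generate_breathing, breathing)
  times <- acquisition_times(acquisition)
  gt <- generate_ground_truth(phantom, trace, times$motion,
                              cp_spacing_mm = cp_spacing_mm,
                              coeff_spec = coeff_spec)
  series <- render_series(phantom, gt, acquisition, seed = seed + 1)
  list(phantom = phantom, trace = trace, ground_truth = gt,
       surrogate = series$surrogate, motion = series$motion,
       acquisition = acquisition, seed = seed)
}
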