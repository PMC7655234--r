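# Ground-truth motion for the synthetic datasets.
#
# The true motion is defined *directly* on the B-spline control-point grids
# of the two sliding regions, as an exact linear function of the two latent
# breathing signals:
#
#   CPD(p, t) = c1(p) * primary(t) + c2(p) * secondary(t) + c0(p)
#
# with c0 chosen so that the reference frame (primary closest to its mean
# over the motion times) has exactly zero displacement. Because the ground
# truth lives in the model class, an ordinary least-squares fit against the
# true signals must recover the generating coefficients exactly, which makes
# parameter recovery an exact end-to-end test.

#' Default spatial coefficient patterns for the ground-truth motion
#'
#' Region 2 (lung/mediastinum/abdomen) carries a dominant SI motion that
#' peaks at the diaphragm and decays towards the lung apex; region 1 (chest
#' wall and everything else) carries a small AP expansion. The hysteresis
#' (secondary-signal) maps are deliberately *not* proportional to the
#' primary maps, so the true motion has rank 2 over time and genuinely needs
#' two signals.
#'
#' @param diaphragm_amplitude_mm Peak-to-peak SI excursion at the diaphragm
#'   per unit primary signal (default 15 mm).
#' @param chestwall_amplitude_mm Peak-to-peak AP chest-wall excursion per
#'   unit primary signal (default 3 mm).
#' @param hysteresis_frac Magnitude of the secondary-signal maps relative to
#'   the primary maps (default 0.12).
#' @param apex_decay_mm,abdo_decay_mm Exponential decay lengths of the SI
#'   motion above / below the diaphragm.
#' @export
coeff_spec_default <- function(diaphragm_amplitude_mm = 15,
                               chestwall_amplitude_mm = 3,
                               hysteresis_frac = 0.12,
                               apex_decay_mm = 55, abdo_decay_mm = 110) {
  list(diaphragm_amplitude_mm = diaphragm_amplitude_mm,
       chestwall_amplitude_mm = chestwall_amplitude_mm,
       hysteresis_frac = hysteresis_frac,
       apex_decay_mm = apex_decay_mm, abdo_decay_mm = abdo_decay_mm)
}

#' Generate ground-truth sliding motion on a control-point grid
#'
#' @param phantom A `phantom_anatomy`.
#' @param trace A `breathing_trace`; `motion_times` must lie inside its span.
#' @param motion_times Times (s) of the motion frames.
#' @param cp_spacing_mm Control-point spacing of the motion grids (default
#'   10 mm).
#' @param coeff_spec Spatial coefficient patterns, see [coeff_spec_default()].
#' @return A `ground_truth` object with `transforms` (one `sliding_transform`
#'   per motion time), `times_s`, `reference_index`, the latent `trace`, the
#'   per-region coefficient arrays `c0`, `c1`, `c2` and the grid geometry.
#' @export
generate_ground_truth <- function(phantom, trace, motion_times,
                                  cp_spacing_mm = 10,
                                  coeff_spec = coeff_spec_default()) {
  if (min(motion_times) < 0 || max(motion_times) > trace$duration_s) {
    stop("motion_times must lie within the trace span", call. = FALSE)
  }
  shape <- dim(phantom$reference_image)
  h <- phantom$pixel_spacing_mm
  template <- control_point_grid(shape, h, cp_spacing_mm)
  gs <- template$grid_shape
  pos_r <- template$origin_mm[1] + (seq_len(gs[1]) - 1) * template$spacing_mm[1]
  pos_c <- template$origin_mm[2] + (seq_len(gs[2]) - 1) * template$spacing_mm[2]
  R <- matrix(pos_r, gs[1], gs[2])
  C <- matrix(pos_c, gs[1], gs[2], byrow = TRUE)
  extent <- (shape - 1) * h

  cs <- coeff_spec
  # Normalize so the configured amplitudes are realized peak-to-peak
  # excursions of this trace's primary signal (not per-unit-signal slopes).
  p_dense <- eval_breathing(trace, seq(min(motion_times), max(motion_times),
                                       length.out = 2000))$primary
  p_pp <- diff(range(p_dense))
  # diaphragm depth (mm) under the dome apex, from the phantom config
  dia_mm <- phantom$config$dia_apex_row * extent[1]
  above <- pmax(dia_mm - R, 0)
  below <- pmax(R - dia_mm, 0)
  env_si <- exp(-above / cs$apex_decay_mm) * exp(-below / cs$abdo_decay_mm)

  A <- cs$diaphragm_amplitude_mm / p_pp
  c1_2 <- array(0, dim = c(gs, 2))
  c1_2[, , 1] <- -A * env_si                 # superior (negative row) at exhale
  c1_2[, , 2] <- 0.15 * A * env_si * (C / extent[2] - 0.4)
  c2_2 <- array(0, dim = c(gs, 2))
  c2_2[, , 1] <- -cs$hysteresis_frac * A * env_si * (0.4 + 0.6 * C / extent[2])
  c2_2[, , 2] <- cs$hysteresis_frac * A * env_si * (1 - R / extent[1])

  Bamp <- cs$chestwall_amplitude_mm / p_pp
  env_cw <- exp(-((R - 0.35 * extent[1]) / (0.35 * extent[1]))^2)
  c1_1 <- array(0, dim = c(gs, 2))
  c1_1[, , 2] <- Bamp * env_cw               # posterior (positive col) at exhale
  c1_1[, , 1] <- -0.2 * Bamp * env_cw
  c2_1 <- array(0, dim = c(gs, 2))
  c2_1[, , 2] <- 0.3 * Bamp * env_cw * (R / extent[1])

  ev <- eval_breathing(trace, motion_times)
  ref_idx <- which.min(abs(ev$primary - mean(ev$primary)))[1]
  p0 <- ev$primary[ref_idx]; q0 <- ev$secondary[ref_idx]
  c0_1 <- -c1_1 * p0 - c2_1 * q0
  c0_2 <- -c1_2 * p0 - c2_2 * q0

  gt <- structure(list(
    times_s = motion_times,
    reference_index = ref_idx,
    trace = trace,
    coefficients = list(
      list(c0 = c0_1, c1 = c1_1, c2 = c2_1),   # region 1: chest wall / rest
      list(c0 = c0_2, c1 = c1_2, c2 = c2_2)),  # region 2: sliding interior
    grid_template = template,
    segmentation = phantom$region_mask,
    image_shape = shape,
    pixel_spacing_mm = h
  ), class = "ground_truth")
  gt$transforms <- lapply(motion_times, function(t) gt_transform_at(gt, t))
  gt
}

#' Ground-truth sliding transform at an arbitrary time
#' @param gt A `ground_truth`.
#' @param t Time in seconds (inside the trace span).
#' @export
gt_transform_at <- function(gt, t) {
  ev <- eval_breathing(gt$trace, t)
  grids <- lapply(gt$coefficients, function(cf) {
    g <- gt$grid_template
    g$displacements <- cf$c1 * ev$primary + cf$c2 * ev$secondary + cf$c0
    g
  })
  sliding_transform(grids, gt$segmentation)
}

# Flatten the CPDs of a sliding transform into one numeric vector
# (region 1 row, region 1 col, region 2 row, region 2 col).
flatten_cpd <- function(transform) {
  c(as.vector(transform$region_grids[[1]]$displacements),
    as.vector(transform$region_grids[[2]]$displacements))
}

# Rebuild a sliding transform from a flat CPD vector and a template.
unflatten_cpd <- function(x, template_transform) {
  m <- prod(template_transform$region_grids[[1]]$grid_shape)
  grids <- template_transform$region_grids
  dim2 <- c(template_transform$region_grids[[1]]$grid_shape, 2)
  grids[[1]]$displacements <- array(x[1:(2 * m)], dim2)
  grids[[2]]$displacements <- array(x[(2 * m + 1):(4 * m)], dim2)
  sliding_transform(grids, template_transform$source_segmentation)
}
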