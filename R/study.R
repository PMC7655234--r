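# End-to-end drivers: from a (synthetic) dataset to the signal set and the
# training-size experiment.

#' Extract the full surrogate-signal set and assemble an evaluable dataset
#'
#' Runs the signal-extraction protocol on a simulated dataset: trims
#' pre-steady-state surrogate frames, tracks diaphragm and skin, selects the
#' reference frame from the first 30 surrogate images, builds the body mask,
#' computes intensity PCA (and, when `registration = TRUE`, registers every
#' surrogate frame to the reference and computes PCA on the resulting
#' control-point displacements), then resamples every signal at the motion
#' times with a smoothing spline. Motion frames outside the surrogate time
#' span are discarded.
#'
#' @param sim Output of [simulate_dataset()].
#' @param registration Compute CPD_s signals via FFD registration of the
#'   surrogate slice (slowest step; disable when only intensity-based and
#'   local signals are needed).
#' @param smoothing_level Passed to [resample_signal()].
#' @param steady_state_threshold Passed to [discard_pre_steady_state()].
#' @param register_args List of overrides for [register_series()].
#' @return A dataset list for [run_experiment()], additionally carrying
#'   `n_pre_steady_discarded`, `n_out_of_span`, `reference_frame_index`,
#'   `body_mask` and the raw (surrogate-time) signals in `raw_signals`.
#' @export
prepare_synthetic_dataset <- function(sim, registration = TRUE,
                                      smoothing_level = NULL,
                                      steady_state_threshold = 0.05,
                                      register_args = list()) {
  ph <- sim$phantom
  trimmed <- discard_pre_steady_state(sim$surrogate, steady_state_threshold)
  surr <- trimmed$series

  dia <- diaphragm_signal(surr, ph$diaphragm_seed_point)
  skin <- skin_signal(surr, ph$skin_seed_point)
  ref_idx <- select_reference_frame(surr, ph$diaphragm_seed_point)
  body <- make_body_mask(surr$frames[, , ref_idx])

  raw <- list(diaphragm = dia, skin = skin)
  pca_int <- pca_intensity(surr, 3, align_signal = dia$sample_values)
  int_sigs <- pca_score_signals(pca_int, prefix = "pc")
  names(int_sigs) <- paste0(names(int_sigs), "_int")
  raw <- c(raw, int_sigs)

  cpd_s <- NULL
  if (registration) {
    if (is.null(register_args$mask)) register_args$mask <- body
    cpd_s <- do.call(register_series,
                     c(list(series = surr, reference_index = ref_idx),
                       register_args))
    pca_c <- pca_cpd(cpd_s, body, surr$pixel_spacing_mm, 3,
                     align_signal = dia$sample_values, times_s = surr$times_s)
    cpd_sigs <- pca_score_signals(pca_c, prefix = "pc")
    names(cpd_sigs) <- paste0(names(cpd_sigs), "_cpd")
    raw <- c(raw, cpd_sigs)
  }

  motion_times <- sim$motion$times_s
  first <- resample_signal(raw[[1]], motion_times, smoothing_level)
  rejected <- attr(first, "rejected_indices")
  accepted <- setdiff(seq_along(motion_times), rejected)
  signals <- lapply(raw, function(s) {
    resample_signal(s, motion_times[accepted], smoothing_level)
  })

  list(signals = signals,
       motion_times = motion_times[accepted],
       reference_transforms = sim$ground_truth$transforms[accepted],
       evaluation_mask = ph$evaluation_mask,
       tumour_mask = ph$tumour_mask,
       image_shape = dim(ph$reference_image),
       pixel_spacing_mm = ph$pixel_spacing_mm,
       body_mask = body,
       reference_frame_index = ref_idx,
       n_pre_steady_discarded = trimmed$n_discarded,
       n_out_of_span = length(rejected),
       raw_signals = raw,
       cpd_s = cpd_s,
       ground_truth = sim$ground_truth)
}

#' Run the complete synthetic study for one seed
#'
#' Simulates a default dataset (optionally with a breath-hold spanning part
#' of the test period), extracts all signals, and runs the training-size /
#' cross-validation experiment over the model zoo.
#'
#' @param seed Integer seed.
#' @param breath_hold `NULL`, or a `list(start_s =, duration_s =)`; `TRUE`
#'   uses the default hold (12 s starting near 22 s at cycle phase 0.35,
#'   inside the building period, so that small training sets contain
#'   degenerate signal/derivative rows as in an irregular breathing
#'   pattern).
#' @param registration Include the CPD_s-based signals/models (needs the
#'   surrogate-slice registration).
#' @param models Model zoo (specs referencing unavailable signals are
#'   dropped automatically).
#' @param n_grid Training sizes.
#' @param acquisition Acquisition configuration.
#' @return The [run_experiment()] results table; the prepared dataset is
#'   attached as attribute `dataset`.
#' @export
run_synthetic_study <- function(seed = 1, breath_hold = NULL,
                                registration = TRUE, models = model_zoo(),
                                n_grid = 20:6,
                                acquisition = acquisition_config()) {
  if (isTRUE(breath_hold)) {
    breath_hold <- list(start_s = 22, duration_s = 12, phase = 0.35)
  }
  sim <- simulate_dataset(seed = seed, acquisition = acquisition,
                          breathing = list(breath_hold = breath_hold))
  ds <- prepare_synthetic_dataset(sim, registration = registration)
  available <- names(ds$signals)
  usable <- Filter(function(s) {
    s$n_signals == 0 || all(s$terms$signal %in% available)
  }, models)
  res <- run_experiment(ds, usable, make_split(length(ds$motion_times),
                                               n_grid = n_grid))
  attr(res, "dataset") <- ds
  res
}
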