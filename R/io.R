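# File formats and configuration: NIfTI series / masks / control-point
# grids, CSV signals, YAML manifests and config validation.

#' Write a cine series as a 3D NIfTI file
#'
#' Slices along the third dimension are frames; in-plane spacing and the
#' frame interval are stored in `pixdim`, the first frame time in `toffset`.
#' Frame times must be regularly spaced for this representation.
#'
#' @param series A `cine_series`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_series <- function(series, path) {
  dts <- diff(series$times_s)
  dt <- mean(dts)
  if (length(dts) && any(abs(dts - dt) > 1e-6 * dt)) {
    stop("NIfTI series storage requires regularly spaced frame times", call. = FALSE)
  }
  img <- RNifti::asNifti(series$frames)
  hdr <- list(pixdim = c(-1, series$pixel_spacing_mm, dt, 1, 1, 1, 1),
              toffset = series$times_s[1],
              xyzt_units = 8L + 2L,     # mm + seconds
              descrip = paste0("cine:", series$orientation, ":", series$role))
  img <- RNifti::asNifti(img, hdr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a cine series written by [write_series()]
#' @param path NIfTI path.
#' @return A `cine_series`.
#' @export
read_series <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  a <- as.array(img)
  a <- array(as.numeric(a), dim = dim(a))
  if (length(dim(a)) != 3) stop(sprintf("%s: expected a 3D series", path), call. = FALSE)
  dt <- hdr$pixdim[4]
  if (!is.finite(dt) || dt <= 0) {
    stop(sprintf("%s: non-positive frame interval in header (duplicated timestamps?)",
                 path), call. = FALSE)
  }
  meta <- strsplit(hdr$descrip, ":")[[1]]
  orientation <- if (length(meta) >= 2 && meta[2] %in% c("sagittal", "coronal"))
    meta[2] else "sagittal"
  role <- if (length(meta) >= 3 && meta[3] %in% c("surrogate", "motion"))
    meta[3] else "surrogate"
  cine_series(a, hdr$toffset + (seq_len(dim(a)[3]) - 1) * dt,
              hdr$pixdim[2:3], orientation, role)
}

#' Write a binary mask as NIfTI
#' @param mask Binary matrix.
#' @param pixel_spacing_mm Spacing.
#' @param path Output path.
#' @export
write_mask <- function(mask, pixel_spacing_mm, path) {
  img <- RNifti::asNifti(array(as.numeric(mask), dim = c(dim(mask), 1)))
  img <- RNifti::asNifti(img, list(pixdim = c(-1, pixel_spacing_mm, 1, 1, 1, 1, 1)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#' @param path NIfTI path.
#' @export
read_mask <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  matrix(as.numeric(a > 0.5), dim(a)[1], dim(a)[2])
}

strip_nifti <- function(a) array(as.numeric(a), dim = dim(a))

#' Write a control-point grid as a 5D NIfTI file
#'
#' Layout compatible with common registration packages: grid rows x cols x
#' 1 x 1 x 2 displacement components (row/SI first), control-point spacing
#' in `pixdim` and the grid origin in the `qoffset` fields.
#'
#' @param grid A `control_point_grid`.
#' @param path Output path.
#' @export
write_cpd <- function(grid, path) {
  a <- array(0, dim = c(grid$grid_shape, 1, 1, 2))
  a[, , 1, 1, 1] <- grid$displacements[, , 1]
  a[, , 1, 1, 2] <- grid$displacements[, , 2]
  img <- RNifti::asNifti(a)
  img <- RNifti::asNifti(img, list(
    pixdim = c(-1, grid$spacing_mm, 1, 1, 1, 1, 1),
    qoffset_x = grid$origin_mm[1], qoffset_y = grid$origin_mm[2],
    qform_code = 1L, descrip = "cpd"))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a control-point grid written by [write_cpd()]
#' @param path NIfTI path.
#' @param expected_spacing_mm Optional check against a manifest value.
#' @export
read_cpd <- function(path, expected_spacing_mm = NULL) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  a <- strip_nifti(as.array(img))
  d <- dim(a)
  if (length(d) != 5 || d[5] != 2) {
    stop(sprintf("%s: expected a 5D control-point file with 2 components", path),
         call. = FALSE)
  }
  spacing <- hdr$pixdim[2:3]
  if (!is.null(expected_spacing_mm) &&
      any(abs(spacing - expected_spacing_mm) > 1e-4)) {
    stop(sprintf("%s: control-point spacing %.3g x %.3g does not match manifest",
                 path, spacing[1], spacing[2]), call. = FALSE)
  }
  disp <- array(0, dim = c(d[1], d[2], 2))
  disp[, , 1] <- a[, , 1, 1, 1]
  disp[, , 2] <- a[, , 1, 1, 2]
  structure(list(origin_mm = c(hdr$qoffset_x, hdr$qoffset_y),
                 spacing_mm = spacing, grid_shape = d[1:2],
                 displacements = disp),
            class = "control_point_grid")
}

#' Write surrogate signals to CSV (`time_s, value, units` per signal)
#' @param signals Named list of `surrogate_signal`s.
#' @param dir Output directory.
#' @export
write_signals_csv <- function(signals, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(signals)) {
    s <- signals[[nm]]
    utils::write.csv(data.frame(time_s = s$sample_times_s, value = s$sample_values,
                                units = s$units),
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}

#' Write the ground-truth latent signals to CSV
#' @param trace A `breathing_trace`.
#' @param path CSV path (`time_s, primary, secondary`).
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$times_s, primary = trace$primary,
                              secondary = trace$secondary),
                   path, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Every tunable default of the pipeline in one nested list; values can be
#' overridden from a YAML file via [load_config()].
#' @export
default_config <- function() {
  list(
    phantom = list(shape = c(128L, 128L), pixel_spacing_mm = c(1.98, 1.98),
                   tumour_radius_mm = 11),
    breathing = list(amplitude = 1, amplitude_sd = 0.1, period_s = 4,
                     period_sd = 0.4, baseline_sd = 0.05, phase_lead = 0.125,
                     breath_hold = NULL),
    acquisition = list(frame_rate_hz = 1.9, duration_s = 63,
                       noise_sd_frac = 0.02,
                       steady_state_inflation = c(1.30, 1.18, 1.09),
                       motion_orientation = "sagittal"),
    motion = list(cp_spacing_mm = 10, diaphragm_amplitude_mm = 15,
                  chestwall_amplitude_mm = 3, hysteresis_frac = 0.12),
    signals = list(steady_state_threshold = 0.05, diaphragm_window = c(20L, 10L),
                   skin_window = c(6L, 20L), reference_k = 30L,
                   closing_radius_px = 6L, n_components = 3L,
                   smoothing_level = NULL),
    registration = list(levels_px = c(20, 10, 5), bend_weight = 0.005,
                        lncc_sigma = 2, warm_start = TRUE, maxit = 100L,
                        refine_maxit = 12L),
    evaluation = list(n_grid = 20:6)
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads YAML, checks every key against [default_config()] (unknown keys are
#' rejected with their path) and merges over the defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_validate <- function(base, override, where) {
    for (key in names(override)) {
      if (!key %in% names(base)) {
        stop(sprintf("unknown configuration key: %s%s", where, key), call. = FALSE)
      }
      if (is.list(base[[key]]) && !is.null(base[[key]]) && is.list(override[[key]])) {
        base[[key]] <- merge_validate(base[[key]], override[[key]],
                                      paste0(where, key, "."))
      } else {
        base[[key]] <- override[[key]]
      }
    }
    base
  }
  merge_validate(cfg, user, "")
}

#' Write a dataset manifest (YAML) tying the files of one dataset together
#' @param entries Named list of relative file paths and metadata.
#' @param path Output YAML path.
#' @export
write_manifest <- function(entries, path) {
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' Read a dataset manifest, checking that referenced files exist
#' @param path Manifest YAML.
#' @export
read_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  base <- dirname(path)
  for (key in names(man)) {
    v <- man[[key]]
    if (is.character(v) && length(v) == 1 && grepl("\\.(nii|nii\\.gz|csv|yaml)$", v)) {
      if (!file.exists(file.path(base, v))) {
        stop(sprintf("manifest entry '%s' refers to missing file %s", key, v),
             call. = FALSE)
      }
    }
  }
  man
}

#' Export a simulated dataset to disk (NIfTI + CSV + manifest)
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory.
#' @return The manifest path.
#' @export
export_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- sim$phantom$pixel_spacing_mm
  write_series(sim$surrogate, file.path(dir, "surrogate.nii.gz"))
  write_series(sim$motion, file.path(dir, "motion.nii.gz"))
  for (nm in c("region_mask", "body_mask", "tumour_mask", "evaluation_mask")) {
    write_mask(sim$phantom[[nm]], h, file.path(dir, paste0(nm, ".nii.gz")))
  }
  write_trace_csv(sim$trace, file.path(dir, "true_signals.csv"))
  cpd_dir <- file.path(dir, "cpd")
  dir.create(cpd_dir, showWarnings = FALSE)
  for (i in seq_along(sim$ground_truth$transforms)) {
    tr <- sim$ground_truth$transforms[[i]]
    write_cpd(tr$region_grids[[1]], file.path(cpd_dir, sprintf("frame%03d_region1.nii.gz", i)))
    write_cpd(tr$region_grids[[2]], file.path(cpd_dir, sprintf("frame%03d_region2.nii.gz", i)))
  }
  man <- list(surrogate_series = "surrogate.nii.gz", motion_series = "motion.nii.gz",
              region_mask = "region_mask.nii.gz", body_mask = "body_mask.nii.gz",
              tumour_mask = "tumour_mask.nii.gz",
              evaluation_mask = "evaluation_mask.nii.gz",
              true_signals = "true_signals.csv", cpd_dir = "cpd",
              pixel_spacing_mm = as.numeric(h),
              cp_spacing_mm = as.numeric(sim$ground_truth$grid_template$spacing_mm),
              orientation = sim$motion$orientation, seed = sim$seed)
  write_manifest(man, file.path(dir, "manifest.yaml"))
  file.path(dir, "manifest.yaml")
}
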