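# Experimental protocol: building/test split, evenly spaced training subsets
# with 4-fold cross-validation, deformation field error (DFE), masked
# statistics and the training-set-size experiment.

#' Build the building/test split plan
#'
#' The first 80 motion frames form the building set, the remainder the test
#' set. Training subsets are evenly spaced (step 4) within the building set:
#' at n = 20 the four cross-validation folds are frames
#' `[1, 5, ..., 77]`, `[2, 6, ..., 78]`, `[3, 7, ..., 79]`, `[4, 8, ..., 80]`;
#' for smaller n the earliest frames are discarded so the frames closest to
#' the test set are retained (fold 1 at n = 19 is `[5, 9, ..., 77]`).
#'
#' @param n_motion_frames Total number of motion frames (>= 81).
#' @param n_grid Training sizes (default 20 down to 6).
#' @return A `split_plan` with `building_indices`, `test_indices`, `n_grid`
#'   and `folds`; use [training_indices()] to materialize a subset. All
#'   indices are 1-based frame numbers.
#' @export
make_split <- function(n_motion_frames, n_grid = 20:6) {
  if (n_motion_frames < 81) {
    stop("need at least 81 motion frames (80 building + 1 test)", call. = FALSE)
  }
  structure(list(building_indices = 1:80,
                 test_indices = 81:n_motion_frames,
                 folds = 1:4, n_grid = n_grid),
            class = "split_plan")
}

#' Training indices of one fold at one training-set size
#' @param plan A `split_plan`.
#' @param fold Fold number, 1 to 4.
#' @param n Training-set size (at most 20).
#' @export
training_indices <- function(plan, fold, n) {
  full <- seq(as.integer(fold), 80L, by = 4L)
  if (n > length(full)) stop("n exceeds the fold's 20 frames", call. = FALSE)
  full[(length(full) - n + 1):length(full)]
}

#' Deformation field error between two displacement fields
#'
#' Per-pixel Euclidean norm of the vector difference, in mm.
#'
#' @param estimated,reference `dvf`s on the same geometry.
#' @return Matrix of per-pixel DFE (mm).
#' @export
compute_dfe <- function(estimated, reference) {
  if (!all(dim(estimated$displacements) == dim(reference$displacements))) {
    stop("DVF geometries differ", call. = FALSE)
  }
  d <- estimated$displacements - reference$displacements
  sqrt(d[, , 1]^2 + d[, , 2]^2)
}

#' Warp a source-image mask to every test frame
#'
#' @param mask Binary matrix on the source image.
#' @param transforms List of reference `sliding_transform`s (one per frame).
#' @param image_shape,pixel_spacing_mm Image geometry.
#' @return List of binary matrices.
#' @export
transport_masks <- function(mask, transforms, image_shape, pixel_spacing_mm) {
  B <- bspline_matrix(transforms[[1]]$region_grids[[1]], image_shape, pixel_spacing_mm)
  lapply(transforms, function(tr) {
    warp_mask(mask, compose_sliding_dvf(tr, image_shape, pixel_spacing_mm, B = B))
  })
}

#' Masked DFE statistics pooled over test frames
#'
#' Pixels inside each frame's mask are pooled over all frames; the pooled
#' mean and 95th percentile (linear interpolation between order statistics)
#' are reported along with per-frame values. Frames whose mask is empty are
#' skipped with a warning.
#'
#' @param dfe_maps List of per-frame DFE matrices.
#' @param masks List of per-frame binary masks (same length).
#' @param mask_name,model_name,n_train,fold Metadata carried into the report.
#' @return A `dfe_report`: `pooled_mean`, `pooled_p95`, `per_frame`
#'   (data.frame), `n_pixels`.
#' @export
masked_stats <- function(dfe_maps, masks, mask_name = "evaluation",
                         model_name = NA, n_train = NA, fold = NA) {
  stopifnot(length(dfe_maps) == length(masks))
  vals <- vector("list", length(dfe_maps))
  per_frame <- data.frame(frame = seq_along(dfe_maps), mean = NA_real_, p95 = NA_real_)
  for (i in seq_along(dfe_maps)) {
    v <- dfe_maps[[i]][masks[[i]] == 1]
    if (!length(v)) {
      warning(sprintf("mask empty in frame %d; skipped", i), call. = FALSE)
      next
    }
    vals[[i]] <- v
    per_frame$mean[i] <- mean(v)
    per_frame$p95[i] <- stats::quantile(v, 0.95, names = FALSE, type = 7)
  }
  pooled <- unlist(vals)
  if (!length(pooled)) stop("mask is empty in every frame", call. = FALSE)
  structure(list(pooled_mean = mean(pooled),
                 pooled_p95 = stats::quantile(pooled, 0.95, names = FALSE, type = 7),
                 per_frame = per_frame, n_pixels = length(pooled),
                 mask_name = mask_name, model_name = model_name,
                 n_train = n_train, fold = fold),
            class = "dfe_report")
}

#' @export
print.dfe_report <- function(x, ...) {
  cat(sprintf("<dfe_report %s mask%s> pooled mean %.3f mm, p95 %.3f mm over %d px / %d frames\n",
              x$mask_name,
              if (is.na(x$model_name)) "" else paste0(", model ", x$model_name),
              x$pooled_mean, x$pooled_p95, x$n_pixels, nrow(x$per_frame)))
  invisible(x)
}

#' Run the full training-size / cross-validation experiment
#'
#' For every model specification, training size and fold: fit on the evenly
#' spaced training subset, estimate the motion at every test time, compose
#' the deformation fields, and accumulate masked DFE statistics against the
#' reference motion; the no-model baseline is evaluated once. The heavy
#' pixel work is batched through precomputed sparse B-spline operators
#' restricted to the pixels that any mask touches.
#'
#' @param dataset List with elements `signals` (named list of
#'   `surrogate_signal`s with splines), `reference_transforms` (list, one
#'   `sliding_transform` per motion frame), `motion_times`,
#'   `evaluation_mask`, `tumour_mask`, `image_shape`, `pixel_spacing_mm`.
#'   [prepare_synthetic_dataset()] produces one.
#' @param models Named list of `model_spec`s (default [model_zoo()]).
#' @param plan A `split_plan` (default from the number of motion frames).
#' @return Long-format `data.frame` with one row per
#'   (model, n_train, fold, mask): `pooled_mean_mm`, `pooled_p95_mm`,
#'   `n_test_frames`, `rank_warning`. Baseline rows carry `n_train = NA`,
#'   `fold = NA`. Attribute `fold_averaged` holds the fold means.
#' @export
run_experiment <- function(dataset, models = model_zoo(), plan = NULL) {
  times <- dataset$motion_times
  n_frames <- length(times)
  if (is.null(plan)) plan <- make_split(n_frames)
  shape <- dataset$image_shape
  h <- dataset$pixel_spacing_mm
  test_idx <- plan$test_indices
  test_idx <- test_idx[test_idx <= n_frames]
  n_test <- length(test_idx)
  ref <- dataset$reference_transforms
  template <- ref[[1]]
  seg <- template$source_segmentation

  # Warped masks per test frame, then restrict all pixel work to their union.
  ev_masks <- transport_masks(dataset$evaluation_mask, ref[test_idx], shape, h)
  tu_masks <- transport_masks(dataset$tumour_mask, ref[test_idx], shape, h)
  union_px <- Reduce(`|`, lapply(seq_len(n_test), function(i) {
    ev_masks[[i]] == 1 | tu_masks[[i]] == 1
  }))
  upx <- which(union_px)                       # linear pixel indices
  n_u <- length(upx)
  in_region2 <- seg[upx] == 1
  B_full <- bspline_matrix(template$region_grids[[1]], shape, h)
  B1 <- B_full[upx[!in_region2], , drop = FALSE]
  B2 <- B_full[upx[in_region2], , drop = FALSE]
  row_of <- integer(n_u)
  row_of[!in_region2] <- seq_len(sum(!in_region2))
  row_of[in_region2] <- sum(!in_region2) + seq_len(sum(in_region2))
  # per-frame mask row indices into the union ordering
  ev_rows <- lapply(ev_masks, function(m) row_of[match(which(m == 1 & union_px), upx)])
  tu_rows <- lapply(tu_masks, function(m) row_of[match(which(m == 1 & union_px), upx)])

  # Reference CPDs as a components x frames matrix.
  m <- prod(template$region_grids[[1]]$grid_shape)
  R_all <- vapply(ref, flatten_cpd, numeric(4 * m))

  # DVF (row, col) over the union pixels for a CPD matrix (components x frames)
  union_dvf <- function(CPD) {
    list(dr = rbind(as.matrix(B1 %*% CPD[1:m, , drop = FALSE]),
                    as.matrix(B2 %*% CPD[2 * m + 1:m, , drop = FALSE])),
         dc = rbind(as.matrix(B1 %*% CPD[m + 1:m, , drop = FALSE]),
                    as.matrix(B2 %*% CPD[3 * m + 1:m, , drop = FALSE])))
  }
  # type-7 (linear interpolation) 95th percentile via partial sort
  fast_p95 <- function(v) {
    n <- length(v)
    pos <- 1 + 0.95 * (n - 1)
    lo <- floor(pos); hi <- ceiling(pos)
    s <- sort(v, partial = unique(c(lo, hi)))
    s[lo] + (pos - lo) * (s[hi] - s[lo])
  }
  mask_idx <- function(rows_list) {
    unlist(lapply(seq_along(rows_list), function(i) rows_list[[i]] + (i - 1) * n_u))
  }
  stats_from_dfe <- function(dfe_u, idx) {
    v <- dfe_u[idx]
    c(mean = mean(v), p95 = fast_p95(v))
  }
  R_test <- R_all[, test_idx, drop = FALSE]
  ref_u <- union_dvf(R_test)
  ev_idx <- mask_idx(ev_rows)
  tu_idx <- mask_idx(tu_rows)

  evaluate_cpds <- function(E) {
    est_u <- union_dvf(E)
    dfe_u <- sqrt((est_u$dr - ref_u$dr)^2 + (est_u$dc - ref_u$dc)^2)
    list(ev = stats_from_dfe(dfe_u, ev_idx), tu = stats_from_dfe(dfe_u, tu_idx))
  }

  rows <- list()
  add_row <- function(model, n, fold, mask, st, warn) {
    rows[[length(rows) + 1]] <<- data.frame(
      model = model, n_train = n, fold = fold, mask = mask,
      pooled_mean_mm = st[["mean"]], pooled_p95_mm = st[["p95"]],
      n_test_frames = n_test, rank_warning = warn)
  }

  base <- evaluate_cpds(matrix(0, 4 * m, n_test))
  add_row("no_model", NA, NA, "evaluation", base$ev, FALSE)
  add_row("no_model", NA, NA, "tumour", base$tu, FALSE)

  fitted_models <- models[vapply(models, function(s) s$n_signals > 0, TRUE)]
  for (spec in fitted_models) {
    X_all <- build_design_matrix(spec, dataset$signals, times)
    warn_design <- isTRUE(attr(X_all, "rank_warning"))
    X_test <- X_all[test_idx, , drop = FALSE]
    for (n in plan$n_grid) {
      for (fold in plan$folds) {
        tr_idx <- training_indices(plan, fold, n)
        Xtr <- X_all[tr_idx, , drop = FALSE]
        sol <- ols_solve(Xtr, t(R_all[, tr_idx, drop = FALSE]))
        E <- t(sol$coef) %*% t(X_test)          # (4m x n_test)
        st <- evaluate_cpds(E)
        warn <- warn_design || sol$rank_deficient
        add_row(spec$name, n, fold, "evaluation", st$ev, warn)
        add_row(spec$name, n, fold, "tumour", st$tu, warn)
      }
    }
  }
  res <- do.call(rbind, rows)
  fa <- stats::aggregate(cbind(pooled_mean_mm, pooled_p95_mm) ~ model + n_train + mask,
                         data = res[!is.na(res$n_train), ], FUN = mean)
  attr(res, "fold_averaged") <- fa
  res
}
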