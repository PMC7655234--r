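# Local surrogate-signal extraction from the surrogate cine series.

#' Discard frames acquired before the intensity steady state
#'
#' Repeated excitation lowers the mean image intensity until a stationary
#' value is reached; frames acquired before that are identified by a simple
#' threshold on the mean intensity and removed. Only a *leading* run of
#' frames is ever removed.
#'
#' @param series A `cine_series`.
#' @param relative_threshold A frame is pre-steady-state if its mean
#'   intensity exceeds `(1 + relative_threshold)` times the median of all
#'   frame mean intensities (default 0.05).
#' @return List with the trimmed `series` and `n_discarded`.
#' @export
discard_pre_steady_state <- function(series, relative_threshold = 0.05) {
  n <- length(series$times_s)
  if (n == 0) stop("series is empty", call. = FALSE)
  means <- apply(series$frames, 3, mean)
  bad <- means > (1 + relative_threshold) * stats::median(means)
  n_discard <- if (bad[1]) which.min(bad) - 1L else 0L
  if (2L * n_discard >= n) {
    stop("no steady state reached: the leading above-threshold run covers the series",
         call. = FALSE)
  }
  if (n_discard > 0) {
    series$frames <- series$frames[, , -(1:n_discard), drop = FALSE]
    series$times_s <- series$times_s[-(1:n_discard)]
  }
  list(series = series, n_discarded = as.integer(n_discard))
}

#' Track an intensity edge with sub-pixel accuracy
#'
#' Within a rectangular window around `seed_point`, every line parallel to
#' `axis` is Gaussian-smoothed (sigma = 1 px), the maximum-|gradient| sample
#' located, and the location refined by a quadratic fit to the three gradient
#' magnitudes around it. The per-frame edge position is the mean of the
#' per-line sub-pixel locations; the signal is the position relative to its
#' own temporal mean, in mm, signed so that end-exhale (superior diaphragm,
#' posterior skin) is positive.
#'
#' @param series A `cine_series`.
#' @param seed_point `(row, col)` pixel coordinates near the edge.
#' @param window `(SI extent, AP extent)` of the tracking window in pixels.
#' @param axis "SI" tracks a horizontal edge along rows (diaphragm), "AP" a
#'   vertical edge along columns (skin).
#' @param min_gradient Minimum |gradient| (fraction of the window dynamic
#'   range) for a line to count; a frame with no valid line is an error
#'   reporting the frame index.
#' @param name Signal name.
#' @return A `surrogate_signal` (mm, zero mean) with attribute
#'   `positions_px`, the absolute sub-pixel edge positions.
#' @export
track_edge <- function(series, seed_point, window, axis = c("SI", "AP"),
                       min_gradient = 0.1, name = "edge") {
  axis <- match.arg(axis)
  shape <- dim(series$frames)[1:2]
  half <- floor(window / 2)
  rows <- (seed_point[1] - half[1]):(seed_point[1] + half[1])
  cols <- (seed_point[2] - half[2]):(seed_point[2] + half[2])
  if (min(rows) < 1 || max(rows) > shape[1] || min(cols) < 1 || max(cols) > shape[2]) {
    stop("tracking window extends outside the image", call. = FALSE)
  }
  n <- length(series$times_s)
  along_rows <- axis == "SI"
  L <- if (along_rows) length(rows) else length(cols)
  if (L < 5) stop("window too short along the tracked axis", call. = FALSE)
  G <- gaussian_operator(L, 1)
  positions <- numeric(n)
  for (t in seq_len(n)) {
    win <- series$frames[rows, cols, t]
    lines <- if (along_rows) win else t(win)   # L x n_lines
    sm <- G %*% lines
    g <- (sm[3:L, , drop = FALSE] - sm[1:(L - 2), , drop = FALSE]) / 2
    ag <- abs(g)
    thresh <- max(min_gradient * diff(range(win)) / 2, 1e-12)
    pos_line <- rep(NA_real_, ncol(ag))
    for (j in seq_len(ncol(ag))) {
      i <- which.max(ag[, j])
      if (ag[i, j] < thresh) next   # line has no usable edge
      im <- max(i - 1, 1); ip <- min(i + 1, nrow(ag))
      denom <- ag[im, j] - 2 * ag[i, j] + ag[ip, j]
      delta <- if (denom < 0) 0.5 * (ag[im, j] - ag[ip, j]) / denom else 0
      pos_line[j] <- i + 1 + pmin(pmax(delta, -0.5), 0.5)   # +1: gradient offset
    }
    if (all(is.na(pos_line))) {
      stop(sprintf("no trackable edge in frame %d (all gradients below threshold)", t),
           call. = FALSE)
    }
    offset <- if (along_rows) rows[1] - 1 else cols[1] - 1
    positions[t] <- offset + mean(pos_line, na.rm = TRUE)
  }
  spacing <- if (along_rows) series$pixel_spacing_mm[1] else series$pixel_spacing_mm[2]
  # exhale-positive: superior diaphragm = decreasing row; posterior skin =
  # increasing column
  sgn <- if (along_rows) -1 else 1
  values <- sgn * (positions - mean(positions)) * spacing
  sig <- surrogate_signal(name, series$times_s, values, units = "mm")
  attr(sig, "positions_px") <- positions
  sig
}

#' Diaphragm surrogate signal (SI displacement, mm, exhale-positive)
#' @inheritParams track_edge
#' @param window Default 20 px SI by 10 px AP.
#' @export
diaphragm_signal <- function(series, seed_point, window = c(20, 10),
                             min_gradient = 0.1) {
  track_edge(series, seed_point, window, axis = "SI",
             min_gradient = min_gradient, name = "diaphragm")
}

#' Skin surrogate signal (AP displacement, mm, exhale-positive)
#' @inheritParams track_edge
#' @param window Default 6 px SI by 20 px AP.
#' @export
skin_signal <- function(series, seed_point, window = c(6, 20),
                        min_gradient = 0.1) {
  track_edge(series, seed_point, window, axis = "AP",
             min_gradient = min_gradient, name = "skin")
}

#' Binary body mask from a reference frame
#'
#' Otsu threshold to separate body from background, morphological closing to
#' recover low-intensity regions such as the lung, then the largest connected
#' component.
#'
#' @param reference_frame Matrix.
#' @param closing_radius_px Disc radius of the closing element.
#' @return Binary matrix.
#' @export
make_body_mask <- function(reference_frame, closing_radius_px = 6) {
  rng <- range(reference_frame)
  if (diff(rng) == 0) stop("constant image: no foreground to segment", call. = FALSE)
  norm <- (reference_frame - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm))
  mask <- (norm > thr) * 1
  if (!any(mask == 1)) stop("empty foreground after thresholding", call. = FALSE)
  if (closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius_px + 1, "disc")
    mask <- EBImage::closing(mask, brush)
  }
  matrix(as.numeric(largest_component(mask) > 0), nrow(reference_frame))
}

#' Select the reference frame of a surrogate series
#'
#' The average diaphragm position is computed from the first `k` frames and
#' the frame whose diaphragm sits closest to that average is returned (ties
#' broken by the earliest index).
#'
#' @param series A `cine_series`.
#' @param seed_point,window Passed to [diaphragm_signal()].
#' @param k Number of leading frames to consider (default 30, covering a few
#'   breath cycles); if the series is shorter, all frames are used with a
#'   warning.
#' @return Frame index.
#' @export
select_reference_frame <- function(series, seed_point, window = c(20, 10), k = 30) {
  n <- length(series$times_s)
  if (n < k) {
    warning(sprintf("series has %d < %d frames; using all of them", n, k), call. = FALSE)
    k <- n
  }
  sub <- series
  sub$frames <- series$frames[, , 1:k, drop = FALSE]
  sub$times_s <- series$times_s[1:k]
  pos <- attr(diaphragm_signal(sub, seed_point, window), "positions_px")
  which.min(abs(pos - mean(pos)))[1]
}
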