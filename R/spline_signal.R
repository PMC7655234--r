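# Surrogate-signal container and smoothing-spline resampling.

#' Surrogate signal
#'
#' A named 1D signal sampled at frame times, optionally carrying a fitted
#' smoothing spline so it (and its temporal derivative) can be evaluated at
#' arbitrary times.
#'
#' @param name Identifier.
#' @param sample_times_s Sample times (s), strictly increasing.
#' @param sample_values Values at those times.
#' @param units One of "mm", "a.u.", "mm/s", "a.u./s".
#' @param spline Optional function `f(t, deriv = 0)`.
#' @export
surrogate_signal <- function(name, sample_times_s, sample_values,
                             units = "a.u.", spline = NULL) {
  if (length(sample_times_s) != length(sample_values)) {
    stop("times and values must have the same length", call. = FALSE)
  }
  if (!all(is.finite(sample_values))) stop("signal values must be finite", call. = FALSE)
  structure(list(name = name, sample_times_s = as.numeric(sample_times_s),
                 sample_values = as.numeric(sample_values),
                 units = units, spline = spline),
            class = "surrogate_signal")
}

#' @export
print.surrogate_signal <- function(x, ...) {
  cat(sprintf("<surrogate_signal '%s'> %d samples over %.1f s [%s], range %.3g..%.3g\n",
              x$name, length(x$sample_times_s),
              diff(range(x$sample_times_s)), x$units,
              min(x$sample_values), max(x$sample_values)))
  invisible(x)
}

#' Resample a surrogate signal at new times with a smoothing spline
#'
#' A cubic smoothing spline is fitted to the signal samples and evaluated at
#' `target_times`. Target times outside the sampled interval are *rejected*
#' (reported via the `rejected_indices` attribute, never silently clipped)
#' so the caller can discard the corresponding motion frames.
#'
#' @param signal A `surrogate_signal`.
#' @param target_times Times (s) at which to evaluate.
#' @param smoothing_level `NULL` (default) picks the smoothing penalty
#'   data-adaptively so the residual RMS matches a noise estimate (median
#'   absolute successive difference / sqrt(2)); `0` interpolates exactly;
#'   any other value is used as the `lambda` of [stats::smooth.spline()].
#' @return A `surrogate_signal` sampled at the accepted target times, with a
#'   fitted `spline` and attribute `rejected_indices` (indices into
#'   `target_times` that fell outside the sampled span).
#' @export
resample_signal <- function(signal, target_times, smoothing_level = NULL) {
  tt <- signal$sample_times_s
  span <- range(tt)
  rejected <- which(target_times < span[1] | target_times > span[2])
  accepted <- setdiff(seq_along(target_times), rejected)
  fit <- fit_signal_spline(signal, smoothing_level)
  out <- surrogate_signal(signal$name, target_times[accepted],
                          fit(target_times[accepted]),
                          units = signal$units, spline = fit)
  attr(out, "rejected_indices") <- rejected
  out
}

# Fit the smoothing spline; returns f(t, deriv = 0).
#
# The default smoothing level is chosen by generalized cross-validation:
# at cine frame rates (~2 fps, ~8 samples per breath) adjacent samples
# differ by genuine motion, so residual-based noise estimators grossly
# over-smooth, while GCV keeps the breathing waveform and still suppresses
# tracking jitter.
fit_signal_spline <- function(signal, smoothing_level = NULL) {
  tt <- signal$sample_times_s
  y <- signal$sample_values
  interpolate <- function() {
    f <- stats::splinefun(tt, y, method = "fmm")   # exact for cubic data
    function(t, deriv = 0) f(t, deriv = deriv)
  }
  if (!is.null(smoothing_level) && smoothing_level == 0) return(interpolate())
  if (stats::sd(y) < 1e-12 * max(abs(y), 1)) return(interpolate())
  s <- if (is.null(smoothing_level)) {
    stats::smooth.spline(tt, y, cv = FALSE, all.knots = TRUE)
  } else {
    stats::smooth.spline(tt, y, lambda = smoothing_level, all.knots = TRUE)
  }
  function(t, deriv = 0) stats::predict(s, t, deriv = deriv)$y
}

#' Temporal derivative of a surrogate signal
#'
#' Analytic first derivative of the fitted smoothing spline, evaluated at
#' the signal's own sample times.
#'
#' @param signal A `surrogate_signal` with a fitted spline (e.g. from
#'   [resample_signal()]).
#' @return A `surrogate_signal` named `<name>_deriv` in `<units>/s`.
#' @export
derivative_signal <- function(signal) {
  if (is.null(signal$spline)) {
    stop("signal has no fitted spline; resample it first", call. = FALSE)
  }
  f <- signal$spline
  surrogate_signal(paste0(signal$name, "_deriv"), signal$sample_times_s,
                   f(signal$sample_times_s, deriv = 1),
                   units = paste0(signal$units, "/s"),
                   spline = function(t, deriv = 0) f(t, deriv = deriv + 1))
}
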