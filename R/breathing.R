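# Respiratory breathing-trace generator.
#
# The primary signal is a Lujan-type raised-cosine-power waveform built
# cycle by cycle, with per-cycle amplitude, period and baseline drawn from
# configurable distributions (breath-to-breath variability). The secondary
# signal is the same waveform evaluated with a phase lead, so that the
# (primary, secondary) trajectory traces hysteresis loops (intra-cycle
# variability). A breath-hold freezes both latents by warping time.

#' Generate a breathing trace with inter-cycle variability and hysteresis
#'
#' Within cycle k starting at `t_k` with period `T_k`, amplitude `a_k` and
#' baseline `b_k` (`u = (t - t_k)/T_k`):
#' `primary(t) = b_k + a_k * (1 - sin(pi*u)^4)` — exhale at the flat top,
#' positive peaks at end-exhalation; `secondary(t)` is the same waveform with
#' a phase lead of `phase_lead` cycles, centred on its cycle mean.
#'
#' @param duration_s Trace duration in seconds.
#' @param sample_rate_hz Sampling rate of the stored samples (the trace can
#'   also be evaluated at arbitrary times with [eval_breathing()]).
#' @param amplitude,amplitude_sd Mean and spread of per-cycle depth
#'   (dimensionless respiratory depth, exhale-positive).
#' @param period_s,period_sd Mean and spread of the cycle period (s).
#' @param baseline_sd Spread of the per-cycle baseline.
#' @param phase_lead Phase lead of the secondary signal in cycles
#'   (default 1/8); 0 gives a degenerate loop with zero enclosed area.
#' @param breath_hold Optional `list(start_s =, duration_s =, phase =)`;
#'   within the hold both signals are frozen at their onset values and the
#'   cycle resumes afterwards. When `phase` (fraction of a cycle, 0 =
#'   end-exhale top) is given, the onset snaps to the first time at or after
#'   `start_s` with that cycle phase, so the hold freezes at a controlled,
#'   typically intermediate, diaphragm level as seen in irregular breathing.
#' @param seed Integer seed; same seed and configuration give bit-identical
#'   traces.
#' @return A `breathing_trace` with `times_s`, `primary`, `secondary`,
#'   `cycle_params` (the drawn per-cycle values) and `breath_hold_intervals`.
#' @export
generate_breathing <- function(duration_s = 63, sample_rate_hz = 20,
                               amplitude = 1, amplitude_sd = 0.1,
                               period_s = 4, period_sd = 0.4,
                               baseline_sd = 0.05, phase_lead = 1 / 8,
                               breath_hold = NULL, seed = 1) {
  if (duration_s <= 0 || sample_rate_hz <= 0) {
    stop("duration and sample rate must be positive", call. = FALSE)
  }
  if (amplitude_sd < 0 || period_sd < 0 || baseline_sd < 0) {
    stop("variability spreads must be non-negative", call. = FALSE)
  }
  if (!is.null(breath_hold)) {
    if (breath_hold$start_s < 0 ||
        breath_hold$start_s + breath_hold$duration_s > duration_s) {
      stop("breath-hold interval lies outside the trace duration", call. = FALSE)
    }
  }
  # Draw cycles to cover the (un-warped) duration plus margin.
  total <- duration_s + 2 * period_s
  cycles <- with_seed(seed, {
    t_start <- numeric(0); per <- amp <- base <- numeric(0)
    t <- 0
    while (t < total) {
      Tk <- max(period_s * 0.3, stats::rnorm(1, period_s, period_sd))
      ak <- max(amplitude * 0.1, stats::rnorm(1, amplitude, amplitude_sd))
      bk <- stats::rnorm(1, 0, baseline_sd)
      t_start <- c(t_start, t); per <- c(per, Tk); amp <- c(amp, ak); base <- c(base, bk)
      t <- t + Tk
    }
    data.frame(t_start = t_start, period = per, amplitude = amp, baseline = base)
  })
  hold <- NULL
  if (!is.null(breath_hold)) {
    start <- breath_hold$start_s
    if (!is.null(breath_hold$phase)) {
      k <- findInterval(start, cycles$t_start)
      cand <- cycles$t_start[k] + breath_hold$phase * cycles$period[k]
      if (cand < start && k < nrow(cycles)) {
        cand <- cycles$t_start[k + 1] + breath_hold$phase * cycles$period[k + 1]
      }
      start <- cand
    }
    hold <- c(start, start + breath_hold$duration_s)
    if (hold[2] > duration_s) {
      stop("breath-hold interval lies outside the trace duration", call. = FALSE)
    }
  }
  trace <- structure(list(
    cycle_params = cycles,
    phase_lead = phase_lead,
    breath_hold_intervals = if (is.null(hold)) list() else list(hold),
    duration_s = duration_s, seed = seed
  ), class = "breathing_trace")
  times <- seq(0, duration_s, by = 1 / sample_rate_hz)
  ev <- eval_breathing(trace, times)
  trace$times_s <- times
  trace$primary <- ev$primary
  trace$secondary <- ev$secondary
  trace
}

#' Evaluate a breathing trace at arbitrary times
#'
#' @param trace A `breathing_trace`.
#' @param times_s Numeric vector of times (s).
#' @return List with `primary` and `secondary` vectors.
#' @export
eval_breathing <- function(trace, times_s) {
  te <- times_s
  for (hold in trace$breath_hold_intervals) {
    te <- ifelse(times_s < hold[1], times_s,
                 ifelse(times_s <= hold[2], hold[1], times_s - (hold[2] - hold[1])))
  }
  cp <- trace$cycle_params
  k <- findInterval(te, cp$t_start)
  k[k < 1] <- 1
  u <- (te - cp$t_start[k]) / cp$period[k]
  u <- pmin(pmax(u, 0), 1)
  primary <- cp$baseline[k] + cp$amplitude[k] * (1 - sin(pi * u)^4)
  u2 <- (u + trace$phase_lead) %% 1
  secondary <- cp$amplitude[k] * ((1 - sin(pi * u2)^4) - 5 / 8)
  list(primary = primary, secondary = secondary)
}
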