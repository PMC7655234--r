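# Linear correspondence models relating surrogate signals to control-point
# displacements:
#
#   M_i(s_1, s_2)      = c_2 s_2 + c_1 s_1 + c_0
#   M_i(s_1, s_2, s_3) = c_3 s_3 + c_2 s_2 + c_1 s_1 + c_0
#
# where M_i is one component of the motion-slice CPD (one control point, one
# displacement direction, one sliding region) and the c_j are fitted by
# ordinary least squares, independently per component.

#' Specify a correspondence model by its surrogate signals
#'
#' @param name Model identifier.
#' @param signals Character vector of signal names; prefix a name with
#'   `"d/"` to use the temporal derivative of that signal (e.g.
#'   `c("diaphragm", "d/diaphragm")`).
#' @return A `model_spec`.
#' @export
model_spec <- function(name, signals) {
  terms <- data.frame(signal = sub("^d/", "", signals),
                      derivative = grepl("^d/", signals),
                      stringsAsFactors = FALSE)
  structure(list(name = name, terms = terms, n_signals = nrow(terms)),
            class = "model_spec")
}

#' The standard model zoo: 7 two-signal and 3 three-signal models
#'
#' Combinations of diaphragm, skin, intensity-PCA and CPD-PCA signals with
#' and without temporal derivatives, as compared in the motion-modelling
#' study, plus the no-model baseline.
#'
#' @return Named list of `model_spec`s; the baseline is named `"no_model"`
#'   and has zero signals.
#' @export
model_zoo <- function() {
  specs <- list(
    model_spec("pc1_cpd+deriv",   c("pc1_cpd", "d/pc1_cpd")),
    model_spec("pc1_int+deriv",   c("pc1_int", "d/pc1_int")),
    model_spec("dia+deriv",       c("diaphragm", "d/diaphragm")),
    model_spec("skin+deriv",      c("skin", "d/skin")),
    model_spec("dia+skin",        c("diaphragm", "skin")),
    model_spec("pc1_pc2_cpd",     c("pc1_cpd", "pc2_cpd")),
    model_spec("pc1_pc2_int",     c("pc1_int", "pc2_int")),
    model_spec("dia+deriv+skin",  c("diaphragm", "d/diaphragm", "skin")),
    model_spec("pc1_pc2_pc3_cpd", c("pc1_cpd", "pc2_cpd", "pc3_cpd")),
    model_spec("pc1_pc2_pc3_int", c("pc1_int", "pc2_int", "pc3_int")),
    structure(list(name = "no_model",
                   terms = data.frame(signal = character(0), derivative = logical(0)),
                   n_signals = 0L), class = "model_spec"))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Build the design matrix of a model specification
#'
#' Columns follow the spec's signal order (derivatives computed analytically
#' from each signal's fitted spline); the last column is the intercept.
#'
#' @param spec A `model_spec`.
#' @param signals Named list of `surrogate_signal`s with fitted splines
#'   covering `times`.
#' @param times Times (s) of the rows.
#' @return Matrix `length(times) x (n_signals + 1)` with attribute
#'   `rank_warning` set when the columns are nearly collinear (condition
#'   number above 1e10).
#' @export
build_design_matrix <- function(spec, signals, times) {
  cols <- lapply(seq_len(spec$n_signals), function(i) {
    nm <- spec$terms$signal[i]
    sig <- signals[[nm]]
    if (is.null(sig)) stop(sprintf("signal '%s' not available", nm), call. = FALSE)
    if (is.null(sig$spline)) stop(sprintf("signal '%s' has no fitted spline", nm),
                                  call. = FALSE)
    span <- range(sig$sample_times_s)
    if (min(times) < span[1] - 1e-9 || max(times) > span[2] + 1e-9) {
      stop(sprintf("times extrapolate beyond signal '%s'", nm), call. = FALSE)
    }
    sig$spline(times, deriv = if (spec$terms$derivative[i]) 1 else 0)
  })
  X <- cbind(do.call(cbind, c(cols, list(matrix(numeric(0), length(times), 0)))),
             intercept = 1)
  cn <- c(ifelse(spec$terms$derivative, paste0("d/", spec$terms$signal),
                 spec$terms$signal), "intercept")
  colnames(X) <- cn
  d <- svd(scale(X, center = FALSE, scale = apply(abs(X), 2, max) + 1e-300))$d
  if (d[length(d)] <= 0 || d[1] / max(d[length(d)], 1e-300) > 1e10) {
    attr(X, "rank_warning") <- TRUE
  }
  X
}

#' Fit a correspondence model by ordinary least squares
#'
#' Every CPD component is fitted independently; the solve is one
#' multi-right-hand-side SVD least squares (numerically stable,
#' minimum-norm under rank deficiency, never normal equations).
#'
#' @param spec A `model_spec`.
#' @param design Design matrix from [build_design_matrix()].
#' @param training_cpds List of `sliding_transform`s, one per design row.
#' @param training_times Optional times of the rows (stored for reporting).
#' @return A `correspondence_model` with `coefficients`
#'   (`(n_signals + 1) x n_components`), the CPD geometry template, and a
#'   `rank_warning` flag.
#' @export
fit_correspondence_model <- function(spec, design, training_cpds,
                                     training_times = NULL) {
  n <- nrow(design)
  if (length(training_cpds) != n) {
    stop("one training transform per design row required", call. = FALSE)
  }
  if (n < ncol(design)) stop("fewer training rows than coefficients", call. = FALSE)
  if (n < spec$n_signals + 2) {
    stop("need at least n_signals + 2 training rows", call. = FALSE)
  }
  Y <- vapply(training_cpds, flatten_cpd,
              numeric(length(flatten_cpd(training_cpds[[1]]))))
  Y <- t(Y)                                    # rows = times, cols = components
  sol <- ols_solve(design, Y)
  coef <- sol$coef
  rownames(coef) <- colnames(design)
  structure(list(spec = spec, coefficients = coef,
                 template = training_cpds[[1]],
                 training_times = training_times,
                 rank_warning = isTRUE(attr(design, "rank_warning")) ||
                   sol$rank_deficient),
            class = "correspondence_model")
}

# Minimum-norm multi-right-hand-side least squares via SVD.
ols_solve <- function(X, Y) {
  sv <- svd(X)
  tol <- max(sv$d) * 1e-10
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  list(coef = sv$v %*% (dinv * (t(sv$u) %*% Y)),
       rank_deficient = any(sv$d <= tol))
}

#' Estimate motion from surrogate-signal values
#'
#' @param model A `correspondence_model`.
#' @param signal_values Numeric vector of the spec's signals at one time
#'   point (spec order, without intercept).
#' @return A `sliding_transform` with the estimated CPDs.
#' @export
estimate_motion <- function(model, signal_values) {
  if (length(signal_values) != model$spec$n_signals) {
    stop("wrong number of signal values for this model", call. = FALSE)
  }
  if (!all(is.finite(signal_values))) stop("signal values must be finite", call. = FALSE)
  x <- c(signal_values, 1)
  unflatten_cpd(as.numeric(crossprod(model$coefficients, x)), model$template)
}

# Batched version: rows of `values` are time points; returns a matrix of
# flattened CPDs (components x times). Internal fast path for evaluation.
estimate_motion_matrix <- function(model, values) {
  X <- cbind(values, 1)
  t(model$coefficients) %*% t(X)
}

#' The no-model baseline: zero estimated motion
#'
#' @param template A `sliding_transform` providing geometry.
#' @return A `sliding_transform` with all displacements zero.
#' @export
no_model_baseline <- function(template) {
  unflatten_cpd(numeric(4 * prod(template$region_grids[[1]]$grid_shape)), template)
}
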