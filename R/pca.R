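# Global surrogate signals: principal component analysis on image
# intensities and on surrogate-slice control-point displacements (CPD_s).

# Shared mean-centred PCA via singular value decomposition.
# X: frames x variables. Returns scores, loadings, variance fractions.
core_pca <- function(X, n_components, align_signal = NULL) {
  n <- nrow(X)
  if (n < n_components + 1) {
    stop("need at least n_components + 1 frames for PCA", call. = FALSE)
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = n_components, nv = n_components)
  d2 <- sv$d^2
  total <- sum(d2)
  frac_all <- if (total > 0) d2 / total else rep(0, length(d2))
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  loadings <- sv$v
  # Deterministic sign convention: score correlates positively with the
  # alignment signal (diaphragm); fall back to making the largest-|loading|
  # entry positive when the correlation is weak or absent.
  for (k in seq_len(n_components)) {
    s <- 0
    if (!is.null(align_signal) && stats::sd(scores[, k]) > 0 &&
        stats::sd(align_signal) > 0) {
      r <- stats::cor(scores[, k], align_signal)
      if (is.finite(r) && abs(r) >= 0.1) s <- sign(r)
    }
    if (s == 0) s <- sign(loadings[which.max(abs(loadings[, k])), k])
    if (s == 0) s <- 1
    scores[, k] <- s * scores[, k]
    loadings[, k] <- s * loadings[, k]
  }
  list(scores = scores, loadings = loadings,
       explained = frac_all[seq_len(n_components)], all_explained = frac_all,
       mean = mu)
}

#' PCA surrogate signals from image intensities
#'
#' Frames are flattened to pixel vectors, mean-centred over frames, and
#' decomposed; the per-frame scores of the leading components are the
#' surrogate signals and the loadings form per-pixel coefficient maps.
#'
#' @param series A `cine_series`.
#' @param n_components Number of components to return (default 3).
#' @param align_signal Optional numeric vector (one value per frame, e.g.
#'   the diaphragm signal) fixing each component's sign so its score
#'   correlates positively with it.
#' @return A `pca_result`: `component_scores` (frames x k),
#'   `coefficient_maps` (list of k matrices), `explained_variance_fraction`,
#'   `all_explained_variance`, `mean_vector_reference` and `times_s`.
#' @export
pca_intensity <- function(series, n_components = 3, align_signal = NULL) {
  shape <- dim(series$frames)[1:2]
  n <- dim(series$frames)[3]
  X <- t(matrix(series$frames, prod(shape), n))
  p <- core_pca(X, n_components, align_signal)
  structure(list(
    component_scores = p$scores,
    coefficient_maps = lapply(seq_len(n_components),
                              function(k) matrix(p$loadings[, k], shape[1], shape[2])),
    explained_variance_fraction = p$explained,
    all_explained_variance = p$all_explained,
    mean_vector_reference = matrix(p$mean, shape[1], shape[2]),
    times_s = series$times_s, kind = "intensity"
  ), class = "pca_result")
}

#' PCA surrogate signals from surrogate-slice control-point displacements
#'
#' Control points whose image-space location falls outside the body mask are
#' excluded; the SI and AP displacement components of the retained points
#' are concatenated (both in mm, unweighted) into one vector per frame and
#' decomposed as in [pca_intensity()]. Coefficient maps are returned per
#' displacement direction.
#'
#' @param cpd_series List of `control_point_grid`s (one per frame, shared
#'   geometry), e.g. from [register_series()].
#' @param body_mask Binary matrix in image space.
#' @param pixel_spacing_mm Image pixel spacing (mm), to locate control
#'   points in the mask.
#' @inheritParams pca_intensity
#' @param times_s Frame times for the scores.
#' @return A `pca_result`; each element of `coefficient_maps` is a list with
#'   `si` and `ap` grid-shaped matrices (NA outside the body).
#' @export
pca_cpd <- function(cpd_series, body_mask, pixel_spacing_mm, n_components = 3,
                    align_signal = NULL, times_s = NULL) {
  g <- cpd_series[[1]]
  gs <- g$grid_shape
  pos_r <- g$origin_mm[1] + (seq_len(gs[1]) - 1) * g$spacing_mm[1]
  pos_c <- g$origin_mm[2] + (seq_len(gs[2]) - 1) * g$spacing_mm[2]
  pr <- round(pos_r / pixel_spacing_mm[1]) + 1
  pc <- round(pos_c / pixel_spacing_mm[2]) + 1
  PR <- matrix(pr, gs[1], gs[2]); PC <- matrix(pc, gs[1], gs[2], byrow = TRUE)
  inside <- PR >= 1 & PR <= nrow(body_mask) & PC >= 1 & PC <= ncol(body_mask)
  keep <- inside
  keep[inside] <- body_mask[cbind(PR[inside], PC[inside])] == 1
  if (!any(keep)) stop("no control points inside the body mask", call. = FALSE)
  X <- t(vapply(cpd_series, function(gr) {
    c(gr$displacements[, , 1][keep], gr$displacements[, , 2][keep])
  }, numeric(2 * sum(keep))))
  p <- core_pca(X, n_components, align_signal)
  m <- sum(keep)
  maps <- lapply(seq_len(n_components), function(k) {
    si <- ap <- matrix(NA_real_, gs[1], gs[2])
    si[keep] <- p$loadings[1:m, k]
    ap[keep] <- p$loadings[(m + 1):(2 * m), k]
    list(si = si, ap = ap)
  })
  structure(list(
    component_scores = p$scores,
    coefficient_maps = maps,
    explained_variance_fraction = p$explained,
    all_explained_variance = p$all_explained,
    mean_vector_reference = p$mean,
    retained_points = keep,
    times_s = times_s, kind = "cpd"
  ), class = "pca_result")
}

#' Turn PCA scores into surrogate signals
#'
#' @param pca A `pca_result` with `times_s`.
#' @param prefix Signal name prefix, e.g. "pc" gives "pc1", "pc2", ...
#' @return Named list of `surrogate_signal`s (units a.u.).
#' @export
pca_score_signals <- function(pca, prefix = "pc") {
  if (is.null(pca$times_s)) stop("pca_result carries no frame times", call. = FALSE)
  k <- ncol(pca$component_scores)
  out <- lapply(seq_len(k), function(i) {
    surrogate_signal(paste0(prefix, i), pca$times_s, pca$component_scores[, i],
                     units = "a.u.")
  })
  names(out) <- paste0(prefix, seq_len(k))
  out
}
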