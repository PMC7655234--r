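# Single-region multi-resolution FFD registration (used to produce the
# control-point displacements CPD_s on the surrogate slices).
#
# The objective is LNCC(warp(source), target) - bend_weight * bending_energy,
# maximized by L-BFGS-B with analytic gradients chained through the cubic
# B-spline. The two-region sliding registration used to produce the reference
# motion in the study is *not* implemented here; reference motion comes from
# synthetic ground truth or imported control-point displacement files.

#' Register two 2D images with a cubic B-spline free-form deformation
#'
#' Multi-resolution single-region registration: each level fits a
#' control-point grid at the given spacing, warm-started from the refined
#' result of the previous (coarser) level. Deterministic given inputs and
#' budget.
#'
#' @param source,target Matrices of the same shape. The recovered field `u`
#'   satisfies `source(x + u(x)/h) ~ target(x)`.
#' @param pixel_spacing_mm Pixel spacing in mm.
#' @param levels_px Strictly decreasing control-point spacings in pixels,
#'   coarse to fine (default 20, 10, 5 as used for surrogate-slice
#'   registration).
#' @param bend_weight Bending-energy weight (default 0.005).
#' @param lncc_sigma Gaussian window (pixels) of the LNCC similarity.
#' @param maxit Iteration cap per level.
#' @param factr L-BFGS-B relative-improvement stopping factor.
#' @param init_grid Optional `control_point_grid` used to initialize the
#'   finest level directly (the coarser levels are then skipped); used for
#'   temporal warm starts across a cine series.
#' @param mask Optional binary matrix restricting the LNCC average.
#' @return The fitted `control_point_grid` at the finest spacing, with
#'   attributes `trace` (objective at each accepted improvement, decreasing),
#'   `converged` (logical) and `similarity` (final LNCC).
#' @export
register_ffd <- function(source, target, pixel_spacing_mm,
                         levels_px = c(20, 10, 5), bend_weight = 0.005,
                         lncc_sigma = 2, maxit = 100, factr = 1e9,
                         init_grid = NULL, mask = NULL, ops_cache = NULL) {
  stopifnot(all(dim(source) == dim(target)))
  if (any(diff(levels_px) >= 0)) stop("levels_px must be strictly decreasing", call. = FALSE)
  shape <- dim(source)
  h <- rep(as.numeric(pixel_spacing_mm), length.out = 2)
  if (!is.null(init_grid)) levels_px <- levels_px[length(levels_px)]
  grid <- init_grid
  out <- NULL
  for (lev in levels_px) {
    new_grid <- control_point_grid(shape, h, lev * h)
    if (!is.null(grid)) new_grid <- transfer_grid(grid, new_grid, shape, h)
    out <- optimize_ffd_level(source, target, new_grid, shape, h,
                              bend_weight, lncc_sigma, maxit, factr, mask,
                              ops_cache)
    grid <- out$grid
  }
  structure(grid, trace = out$trace, converged = out$converged,
            similarity = out$similarity, class = "control_point_grid")
}

# Initialize a grid by sampling the displacement field of another grid at the
# new control-point locations (clamped into the image extent).
transfer_grid <- function(from, to, image_shape, pixel_spacing_mm) {
  extent <- (image_shape - 1) * pixel_spacing_mm
  pr <- to$origin_mm[1] + (seq_len(to$grid_shape[1]) - 1) * to$spacing_mm[1]
  pc <- to$origin_mm[2] + (seq_len(to$grid_shape[2]) - 1) * to$spacing_mm[2]
  pts <- cbind(rep(pmin(pmax(pr, 0), extent[1]), times = to$grid_shape[2]),
               rep(pmin(pmax(pc, 0), extent[2]), each = to$grid_shape[1]))
  Bp <- bspline_matrix_points(from, pts)
  to$displacements[, , 1] <- as.numeric(Bp %*% as.vector(from$displacements[, , 1]))
  to$displacements[, , 2] <- as.numeric(Bp %*% as.vector(from$displacements[, , 2]))
  to
}

optimize_ffd_level <- function(source, target, grid, shape, h,
                               bend_weight, lncc_sigma, maxit, factr, mask,
                               ops_cache = NULL) {
  n_px <- prod(shape)
  key <- paste0("ops_", paste(grid$grid_shape, collapse = "x"), "_", lncc_sigma)
  ops <- if (!is.null(ops_cache) && !is.null(ops_cache[[key]])) ops_cache[[key]] else {
    B <- bspline_matrix(grid, shape, h)
    bend <- bending_operators(grid, shape, h)
    o <- list(B = B, Bt = Matrix::t(B), bend = bend,
              Q = (Matrix::t(bend$Brr) %*% bend$Brr +
                   2 * Matrix::t(bend$Brc) %*% bend$Brc +
                   Matrix::t(bend$Bcc) %*% bend$Bcc) * (2 / n_px),
              Gr = gaussian_operator(shape[1], lncc_sigma),
              Gc = gaussian_operator(shape[2], lncc_sigma))
    if (!is.null(ops_cache)) ops_cache[[key]] <- o
    o
  }
  B <- ops$B; Bt <- ops$Bt; bend <- ops$bend; Q <- ops$Q
  Gr <- ops$Gr; Gc <- ops$Gc
  sm  <- function(x) Gr %*% x %*% t(Gc)
  smT <- function(x) t(Gr) %*% x %*% Gc
  eps_t <- 1e-6 * diff(range(target))^2 + 1e-30
  ta <- target
  ma <- sm(ta); va <- pmax(sm(ta * ta) - ma^2, 0) + eps_t
  # source intensity gradients (per pixel unit), sampled at warped positions
  grad_r <- source; grad_c <- source
  nr <- shape[1]; nc <- shape[2]
  grad_r[2:(nr - 1), ] <- (source[3:nr, ] - source[1:(nr - 2), ]) / 2
  grad_r[c(1, nr), ] <- source[c(2, nr), ] - source[c(1, nr - 1), ]
  grad_c[, 2:(nc - 1)] <- (source[, 3:nc] - source[, 1:(nc - 2)]) / 2
  grad_c[, c(1, nc)] <- source[, c(2, nc)] - source[, c(1, nc - 1)]
  base_r <- rep(seq_len(nr), times = nc)
  base_c <- rep(seq_len(nc), each = nr)
  mask_w <- if (is.null(mask)) matrix(1, nr, nc) else (mask == 1) * 1
  n_eff <- sum(mask_w)

  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  evaluate <- function(par) {
    m <- prod(grid$grid_shape)
    vr <- par[1:m]; vc <- par[(m + 1):(2 * m)]
    wr <- base_r + as.numeric(B %*% vr) / h[1]
    wc <- base_c + as.numeric(B %*% vc) / h[2]
    smp <- interp_bilinear_multi(list(source, grad_r, grad_c), wr, wc)
    b <- matrix(smp[[1]], nr, nc)
    mb <- sm(b); vb <- pmax(sm(b * b) - mb^2, 0) + eps_t
    cv <- sm(ta * b) - ma * mb
    isab <- 1 / sqrt(va * vb)
    rho <- cv * isab
    sim <- sum(rho * mask_w) / n_eff
    # d(-sim)/db, adjoint-smoothed
    w1 <- isab * mask_w
    w2 <- cv * isab / vb * mask_w
    gb <- (ta * smT(w1) - smT(ma * w1) - b * smT(w2) + smT(mb * w2)) / n_eff
    fr <- gb * matrix(smp[[2]], nr, nc) / h[1]
    fc <- gb * matrix(smp[[3]], nr, nc) / h[2]
    g_sim <- c(as.numeric(Bt %*% as.vector(fr)), as.numeric(Bt %*% as.vector(fc)))
    be <- (sum(as.numeric(bend$Brr %*% vr)^2) + 2 * sum(as.numeric(bend$Brc %*% vr)^2) +
           sum(as.numeric(bend$Bcc %*% vr)^2) +
           sum(as.numeric(bend$Brr %*% vc)^2) + 2 * sum(as.numeric(bend$Brc %*% vc)^2) +
           sum(as.numeric(bend$Bcc %*% vc)^2)) / n_px
    g_be <- c(as.numeric(Q %*% vr), as.numeric(Q %*% vc))
    f <- -sim + bend_weight * be
    cache$par <- par
    cache$f <- f
    cache$g <- -g_sim + bend_weight * g_be
    cache$sim <- sim
    f
  }
  trace <- numeric(0)
  fn <- function(par) {
    f <- evaluate(par)
    if (!length(trace) || f < min(trace)) trace[length(trace) + 1] <<- f
    f
  }
  gr_fn <- function(par) {
    if (is.null(cache$par) || !identical(cache$par, par)) evaluate(par)
    cache$g
  }
  par0 <- c(as.vector(grid$displacements[, , 1]), as.vector(grid$displacements[, , 2]))
  res <- stats::optim(par0, fn, gr_fn, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = factr))
  m <- prod(grid$grid_shape)
  grid$displacements[, , 1] <- res$par[1:m]
  grid$displacements[, , 2] <- res$par[(m + 1):(2 * m)]
  if (res$convergence == 1) {
    warning("FFD registration hit the iteration budget; returning best so far",
            call. = FALSE)
  }
  evaluate(res$par)
  list(grid = grid, trace = trace, converged = res$convergence == 0,
       similarity = cache$sim)
}

#' Register every frame of a cine series to a reference frame
#'
#' The reference frame gets a zero grid; every other frame is registered with
#' [register_ffd()]. By default frames are processed in order of distance
#' from the reference and warm-started from the nearest already-registered
#' frame (temporal coherence of breathing makes this both faster and better
#' conditioned); the first frame on each side runs the full multi-resolution
#' schedule.
#'
#' @param series A `cine_series`.
#' @param reference_index Index of the reference frame.
#' @param warm_start Use the neighbouring frame's result to initialize the
#'   finest level (TRUE) or run the full schedule per frame (FALSE).
#' @param refine_maxit Iteration cap per warm-started frame.
#' @inheritParams register_ffd
#' @return List of `control_point_grid`, one per frame.
#' @export
register_series <- function(series, reference_index, levels_px = c(20, 10, 5),
                            bend_weight = 0.005, lncc_sigma = 2,
                            warm_start = TRUE, maxit = 100, refine_maxit = 12,
                            factr = 1e10, mask = NULL) {
  n <- length(series$times_s)
  src <- series$frames[, , reference_index]
  grids <- vector("list", n)
  cache_env <- new.env(parent = emptyenv())
  zero <- control_point_grid(dim(src), series$pixel_spacing_mm,
                             levels_px[length(levels_px)] * series$pixel_spacing_mm)
  grids[[reference_index]] <- zero
  sides <- list()
  if (reference_index < n) sides <- c(sides, list((reference_index + 1):n))
  if (reference_index > 1) sides <- c(sides, list((reference_index - 1):1))
  for (side in sides) {
    prev <- NULL
    for (t in side) {
      tgt <- series$frames[, , t]
      if (warm_start && !is.null(prev)) {
        grids[[t]] <- suppressWarnings(
          register_ffd(src, tgt, series$pixel_spacing_mm, levels_px, bend_weight,
                       lncc_sigma, maxit = refine_maxit, factr = factr,
                       init_grid = prev, mask = mask, ops_cache = cache_env))
      } else {
        grids[[t]] <- suppressWarnings(
          register_ffd(src, tgt, series$pixel_spacing_mm, levels_px, bend_weight,
                       lncc_sigma, maxit = maxit, factr = factr, mask = mask,
                       ops_cache = cache_env))
      }
      prev <- grids[[t]]
    }
  }
  grids
}
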