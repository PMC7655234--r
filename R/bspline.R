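# Cubic B-spline free-form deformation machinery.
#
# Conventions (used by every module):
#   * images are R matrices; row index = SI (increasing inferior),
#     column index = AP (sagittal) or LR (coronal); 1-based;
#   * physical position of pixel (r, c) is ((r-1)*h_r, (c-1)*h_c) mm;
#   * displacements are stored in mm as (row-displacement, col-displacement)
#     and are forward displacements of reference-image anatomy.

cubic_bspline_weights <- function(u, deriv = 0L) {
  # Weights of the 4 control points supporting parameter u in [0, 1):
  # columns correspond to control points i-1, i, i+1, i+2 (0-based i=floor).
  if (deriv == 0L) {
    cbind((1 - u)^3 / 6,
          (3 * u^3 - 6 * u^2 + 4) / 6,
          (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
          u^3 / 6)
  } else if (deriv == 1L) {
    cbind(-(1 - u)^2 / 2,
          (3 * u^2 - 4 * u) / 2,
          (-3 * u^2 + 2 * u + 1) / 2,
          u^2 / 2)
  } else if (deriv == 2L) {
    cbind(1 - u, 3 * u - 2, -3 * u + 1, u)
  } else stop("deriv must be 0, 1 or 2")
}

#' Create a cubic B-spline control-point grid
#'
#' The grid covers the image with at least one control point of margin beyond
#' every border, as required by the cubic basis support.
#'
#' @param image_shape Integer vector `(rows, cols)` of the image the grid
#'   parameterizes.
#' @param pixel_spacing_mm Per-axis pixel spacing in mm.
#' @param cp_spacing_mm Per-axis control-point spacing in mm (scalar recycled).
#' @param displacements Optional array `(grid_rows, grid_cols, 2)` of
#'   control-point displacements in mm; defaults to zero.
#' @return A `control_point_grid` object with fields `origin_mm`,
#'   `spacing_mm`, `grid_shape` and `displacements`.
#' @export
control_point_grid <- function(image_shape, pixel_spacing_mm, cp_spacing_mm,
                               displacements = NULL) {
  cp_spacing_mm <- rep(as.numeric(cp_spacing_mm), length.out = 2)
  pixel_spacing_mm <- rep(as.numeric(pixel_spacing_mm), length.out = 2)
  if (any(cp_spacing_mm <= 0) || any(pixel_spacing_mm <= 0)) {
    stop("spacings must be positive", call. = FALSE)
  }
  extent <- (image_shape - 1) * pixel_spacing_mm
  grid_shape <- as.integer(floor(extent / cp_spacing_mm) + 4)
  g <- list(origin_mm = -cp_spacing_mm,
            spacing_mm = cp_spacing_mm,
            grid_shape = grid_shape,
            displacements = displacements %||%
              array(0, dim = c(grid_shape, 2)))
  if (!all(dim(g$displacements) == c(grid_shape, 2))) {
    stop("displacements have wrong shape for this grid", call. = FALSE)
  }
  class(g) <- "control_point_grid"
  g
}

# 1-D index/weight decomposition for coordinates (mm) against a grid axis.
bspline_axis <- function(coord_mm, origin_mm, spacing_mm, n_cp, deriv = 0L,
                         axis_name = "axis") {
  s <- (coord_mm - origin_mm) / spacing_mm
  i <- floor(s)
  if (any(i < 1) || any(i > n_cp - 3)) {
    stop(sprintf("control point grid does not cover the image along the %s border",
                 axis_name), call. = FALSE)
  }
  w <- cubic_bspline_weights(s - i, deriv)
  if (deriv > 0L) w <- w / spacing_mm^deriv
  list(i = as.integer(i), w = w)
}

#' Sparse evaluation operator of a B-spline grid on the pixel lattice
#'
#' Returns the sparse matrix `B` such that `B %*% as.vector(cpd_component)`
#' gives that displacement component at every pixel (column-major pixel
#' order). Mixed partial derivatives are available through `deriv`.
#'
#' @param grid A `control_point_grid` (only its geometry is used).
#' @param image_shape Image shape `(rows, cols)`.
#' @param pixel_spacing_mm Pixel spacing in mm.
#' @param deriv Integer pair: derivative order along (row, col) axes.
#' @return A `dgCMatrix` of dimension `prod(image_shape) x prod(grid_shape)`.
#' @export
bspline_matrix <- function(grid, image_shape, pixel_spacing_mm, deriv = c(0L, 0L)) {
  pixel_spacing_mm <- rep(as.numeric(pixel_spacing_mm), length.out = 2)
  nr <- image_shape[1]; nc <- image_shape[2]
  ax_r <- bspline_axis((seq_len(nr) - 1) * pixel_spacing_mm[1],
                       grid$origin_mm[1], grid$spacing_mm[1],
                       grid$grid_shape[1], deriv[1], "row")
  ax_c <- bspline_axis((seq_len(nc) - 1) * pixel_spacing_mm[2],
                       grid$origin_mm[2], grid$spacing_mm[2],
                       grid$grid_shape[2], deriv[2], "col")
  build_tensor_operator(ax_r, ax_c, nr, nc, grid$grid_shape)
}

# Same operator for an arbitrary list of points (rows of pts_mm).
bspline_matrix_points <- function(grid, pts_mm, deriv = c(0L, 0L)) {
  ax_r <- bspline_axis(pts_mm[, 1], grid$origin_mm[1], grid$spacing_mm[1],
                       grid$grid_shape[1], deriv[1], "row")
  ax_c <- bspline_axis(pts_mm[, 2], grid$origin_mm[2], grid$spacing_mm[2],
                       grid$grid_shape[2], deriv[2], "col")
  n <- nrow(pts_mm)
  Gr <- grid$grid_shape[1]
  ii <- jj <- xx <- vector("list", 16)
  k <- 1
  for (b in 0:3) for (a in 0:3) {
    ii[[k]] <- seq_len(n)
    jj[[k]] <- (ax_r$i + a) + (ax_c$i + b - 1L) * Gr
    xx[[k]] <- ax_r$w[, a + 1] * ax_c$w[, b + 1]
    k <- k + 1
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, prod(grid$grid_shape)))
}

build_tensor_operator <- function(ax_r, ax_c, nr, nc, grid_shape) {
  Gr <- grid_shape[1]
  pix_r <- rep(seq_len(nr), times = nc)
  pix_c <- rep(seq_len(nc), each = nr)
  ir <- ax_r$i[pix_r]; ic <- ax_c$i[pix_c]
  n <- nr * nc
  ii <- jj <- xx <- vector("list", 16)
  k <- 1
  for (b in 0:3) for (a in 0:3) {
    ii[[k]] <- seq_len(n)
    jj[[k]] <- (ir + a) + (ic + b - 1L) * Gr
    xx[[k]] <- ax_r$w[pix_r, a + 1] * ax_c$w[pix_c, b + 1]
    k <- k + 1
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, prod(grid_shape)))
}

#' Evaluate a B-spline control-point grid into a dense displacement field
#'
#' @param grid A `control_point_grid` with displacements in mm.
#' @param image_shape Image shape `(rows, cols)`.
#' @param pixel_spacing_mm Pixel spacing in mm.
#' @param B Optional precomputed operator from [bspline_matrix()] (reused for
#'   speed in inner loops).
#' @return A `dvf` object: per-pixel displacement array `(rows, cols, 2)` in
#'   mm plus the pixel spacing.
#' @export
evaluate_bspline <- function(grid, image_shape, pixel_spacing_mm, B = NULL) {
  if (is.null(B)) B <- bspline_matrix(grid, image_shape, pixel_spacing_mm)
  u <- array(0, dim = c(image_shape, 2))
  u[, , 1] <- as.numeric(B %*% as.vector(grid$displacements[, , 1]))
  u[, , 2] <- as.numeric(B %*% as.vector(grid$displacements[, , 2]))
  dvf(u, pixel_spacing_mm)
}

#' Construct a deformation vector field object
#'
#' @param displacements Array `(rows, cols, 2)` of per-pixel displacements in
#'   mm (row component first).
#' @param pixel_spacing_mm Pixel spacing in mm.
#' @export
dvf <- function(displacements, pixel_spacing_mm) {
  stopifnot(length(dim(displacements)) == 3, dim(displacements)[3] == 2)
  if (!all(is.finite(displacements))) stop("DVF must be finite everywhere", call. = FALSE)
  structure(list(displacements = displacements,
                 pixel_spacing_mm = rep(as.numeric(pixel_spacing_mm), length.out = 2)),
            class = "dvf")
}

#' Two-region sliding transform
#'
#' Bundles one full control-point grid per sliding region (index 1 = chest
#' wall and everything outside the segmentation, index 2 = the
#' lung/mediastinum/abdomen region where the segmentation is 1) together with
#' the source-image segmentation that selects between them.
#'
#' @param region_grids List of exactly two `control_point_grid`s sharing
#'   geometry; first = chest wall/rest, second = sliding internal region.
#' @param source_segmentation Binary matrix on the reference image (1 =
#'   internal sliding region).
#' @export
sliding_transform <- function(region_grids, source_segmentation) {
  stopifnot(length(region_grids) == 2)
  g1 <- region_grids[[1]]; g2 <- region_grids[[2]]
  if (!isTRUE(all.equal(g1$origin_mm, g2$origin_mm)) ||
      !identical(g1$grid_shape, g2$grid_shape) ||
      !isTRUE(all.equal(g1$spacing_mm, g2$spacing_mm))) {
    stop("both region grids must share geometry", call. = FALSE)
  }
  structure(list(region_grids = region_grids,
                 source_segmentation = source_segmentation),
            class = "sliding_transform")
}

#' Compose the deformation field of a two-region sliding transform
#'
#' Each pixel takes its displacement from the grid of the region it belongs
#' to in the source segmentation; discontinuities across the region boundary
#' are permitted (that is the point of the sliding parameterization).
#'
#' @inheritParams evaluate_bspline
#' @param transform A `sliding_transform`.
#' @export
compose_sliding_dvf <- function(transform, image_shape, pixel_spacing_mm, B = NULL) {
  d1 <- evaluate_bspline(transform$region_grids[[1]], image_shape, pixel_spacing_mm, B)
  d2 <- evaluate_bspline(transform$region_grids[[2]], image_shape, pixel_spacing_mm, B)
  sel <- transform$source_segmentation == 1
  u <- d1$displacements
  u1 <- u[, , 1]; u2 <- u[, , 2]
  u1[sel] <- d2$displacements[, , 1][sel]
  u2[sel] <- d2$displacements[, , 2][sel]
  u[, , 1] <- u1; u[, , 2] <- u2
  dvf(u, pixel_spacing_mm)
}

#' Jacobian determinant of a deformation
#'
#' Determinant of `I + grad(u)` per pixel: 1 means no local area change,
#' values <= 0 indicate folding. Analytic B-spline derivatives are used when a
#' control-point grid is supplied; central differences when a raw DVF is.
#'
#' @param x A `control_point_grid`, `sliding_transform` or `dvf`.
#' @param image_shape,pixel_spacing_mm Required when `x` is a grid or
#'   sliding transform.
#' @return Matrix of per-pixel determinants.
#' @export
jacobian_determinant <- function(x, image_shape = NULL, pixel_spacing_mm = NULL) {
  if (inherits(x, "sliding_transform")) {
    j1 <- jacobian_determinant(x$region_grids[[1]], image_shape, pixel_spacing_mm)
    j2 <- jacobian_determinant(x$region_grids[[2]], image_shape, pixel_spacing_mm)
    sel <- x$source_segmentation == 1
    j1[sel] <- j2[sel]
    return(j1)
  }
  if (inherits(x, "control_point_grid")) {
    Br <- bspline_matrix(x, image_shape, pixel_spacing_mm, deriv = c(1L, 0L))
    Bc <- bspline_matrix(x, image_shape, pixel_spacing_mm, deriv = c(0L, 1L))
    vr <- as.vector(x$displacements[, , 1]); vc <- as.vector(x$displacements[, , 2])
    durdr <- as.numeric(Br %*% vr); durdc <- as.numeric(Bc %*% vr)
    ducdr <- as.numeric(Br %*% vc); ducdc <- as.numeric(Bc %*% vc)
    det <- (1 + durdr) * (1 + ducdc) - durdc * ducdr
    return(matrix(det, image_shape[1], image_shape[2]))
  }
  if (inherits(x, "dvf")) {
    h <- x$pixel_spacing_mm
    gr <- function(m, axis) {
      n <- dim(m)[axis]
      d <- apply(m, 3 - axis, function(v) {
        c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1])
      })
      if (axis == 1) d else t(d)
    }
    ur <- x$displacements[, , 1]; uc <- x$displacements[, , 2]
    det <- (1 + gr(ur, 1) / h[1]) * (1 + gr(uc, 2) / h[2]) -
      (gr(ur, 2) / h[2]) * (gr(uc, 1) / h[1])
    return(det)
  }
  stop("unsupported input", call. = FALSE)
}

#' Warp an image through a displacement field
#'
#' `output(x) = input(x + u(x) / spacing)`; reads outside the image return 0.
#'
#' @param image Matrix.
#' @param dvf A `dvf` on the same pixel grid.
#' @param interpolation "linear" or "nearest".
#' @export
warp_image <- function(image, dvf, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(all(dim(image) == dim(dvf$displacements)[1:2]))
  nr <- nrow(image); nc <- ncol(image)
  h <- dvf$pixel_spacing_mm
  r <- rep(seq_len(nr), times = nc) + as.vector(dvf$displacements[, , 1]) / h[1]
  c <- rep(seq_len(nc), each = nr) + as.vector(dvf$displacements[, , 2]) / h[2]
  v <- if (interpolation == "linear") interp_bilinear(image, r, c)
       else interp_nearest(image, r, c)
  matrix(v, nr, nc)
}

#' Warp a binary mask (nearest-neighbour, re-binarized)
#' @inheritParams warp_image
#' @param mask Binary matrix.
#' @export
warp_mask <- function(mask, dvf) {
  (warp_image(mask, dvf, interpolation = "nearest") > 0.5) * 1
}

#' Invert a displacement field by fixed-point iteration
#'
#' Solves `v(x) = -u(x + v(x))` so that warping with `v` pulls intensities
#' back through the forward field `u`. Used only when rendering synthetic
#' frames; iteration stops when the maximum update falls below `tol_px`
#' pixels.
#'
#' @param dvf Forward `dvf`.
#' @param n_iter Maximum iterations.
#' @param tol_px Convergence tolerance in pixels.
#' @param init Optional `dvf` used as the starting guess (e.g. the inverse
#'   of a temporally adjacent field).
#' @export
invert_dvf <- function(dvf, n_iter = 20, tol_px = 0.01, init = NULL) {
  u <- dvf$displacements
  h <- dvf$pixel_spacing_mm
  nr <- dim(u)[1]; nc <- dim(u)[2]
  ur <- u[, , 1]; uc <- u[, , 2]
  base_r <- rep(seq_len(nr), times = nc)
  base_c <- rep(seq_len(nc), each = nr)
  if (is.null(init)) {
    vr <- vc <- numeric(nr * nc)
  } else {
    vr <- as.vector(init$displacements[, , 1])
    vc <- as.vector(init$displacements[, , 2])
  }
  tol_mm <- tol_px * min(h)
  for (k in seq_len(n_iter)) {
    s <- interp_bilinear_multi(list(ur, uc), base_r + vr / h[1], base_c + vc / h[2])
    new_vr <- -s[[1]]; new_vc <- -s[[2]]
    delta <- max(abs(new_vr - vr), abs(new_vc - vc))
    vr <- new_vr; vc <- new_vc
    if (delta < tol_mm) break
  }
  v <- array(0, dim = c(nr, nc, 2))
  v[, , 1] <- vr; v[, , 2] <- vc
  dvf(v, h)
}

#' Locally normalized cross-correlation between two images
#'
#' Gaussian-windowed local means, variances and covariance give a per-pixel
#' correlation; the similarity is its mean over the image (or a mask). A
#' variance floor avoids division by zero in flat regions.
#'
#' @param a,b Matrices of the same shape.
#' @param sigma_px Gaussian window standard deviation in pixels.
#' @param mask Optional binary matrix restricting the mean.
#' @param eps Variance floor; defaults to `1e-8` times the squared dynamic
#'   range of each image.
#' @return Scalar in `[-1, 1]`.
#' @export
lncc <- function(a, b, sigma_px = 2, mask = NULL, eps = NULL) {
  stopifnot(all(dim(a) == dim(b)))
  eps_a <- eps %||% (1e-8 * diff(range(a))^2 + 1e-30)
  eps_b <- eps %||% (1e-8 * diff(range(b))^2 + 1e-30)
  Gr <- gaussian_operator(nrow(a), sigma_px)
  Gc <- gaussian_operator(ncol(a), sigma_px)
  sm <- function(x) gaussian_blur(x, sigma_px, Gr, Gc)
  ma <- sm(a); mb <- sm(b)
  va <- pmax(sm(a * a) - ma^2, 0) + eps_a
  vb <- pmax(sm(b * b) - mb^2, 0) + eps_b
  cov <- sm(a * b) - ma * mb
  rho <- cov / sqrt(va * vb)
  if (is.null(mask)) mean(rho) else mean(rho[mask == 1])
}

#' Bending energy of a B-spline displacement field
#'
#' Mean over the pixel domain of the sum of squared second spatial
#' derivatives of both displacement components, with the mixed term counted
#' twice. Zero for any globally affine field.
#'
#' @inheritParams evaluate_bspline
#' @param ops Optional precomputed operators from `bending_operators()`.
#' @export
bending_energy <- function(grid, image_shape, pixel_spacing_mm, ops = NULL) {
  if (is.null(ops)) ops <- bending_operators(grid, image_shape, pixel_spacing_mm)
  v <- cbind(as.vector(grid$displacements[, , 1]),
             as.vector(grid$displacements[, , 2]))
  n <- prod(image_shape)
  tot <- 0
  for (comp in 1:2) {
    tot <- tot + sum(as.numeric(ops$Brr %*% v[, comp])^2) +
      2 * sum(as.numeric(ops$Brc %*% v[, comp])^2) +
      sum(as.numeric(ops$Bcc %*% v[, comp])^2)
  }
  tot / n
}

bending_operators <- function(grid, image_shape, pixel_spacing_mm) {
  list(Brr = bspline_matrix(grid, image_shape, pixel_spacing_mm, deriv = c(2L, 0L)),
       Brc = bspline_matrix(grid, image_shape, pixel_spacing_mm, deriv = c(1L, 1L)),
       Bcc = bspline_matrix(grid, image_shape, pixel_spacing_mm, deriv = c(0L, 2L)))
}
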