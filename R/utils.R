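# Internal helpers shared across modules.

#' Run an expression with a temporary RNG state
#'
#' All stochastic generators in the package funnel their randomness through
#' this helper so that a single integer seed makes every output bit-identical,
#' without disturbing the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Bilinear interpolation of a matrix at fractional pixel coordinates
#'
#' @param img Matrix.
#' @param r,c Numeric vectors of 1-based row/column coordinates.
#' @param mode "zero" returns 0 outside the image, "clamp" extends border
#'   values (used for displacement-field inversion).
#' @return Numeric vector of interpolated values.
#' @keywords internal
#' @noRd
interp_bilinear <- function(img, r, c, mode = c("zero", "clamp")) {
  mode <- match.arg(mode)
  nr <- nrow(img); nc <- ncol(img)
  out <- numeric(length(r))
  if (mode == "clamp") {
    r <- pmin(pmax(r, 1), nr)
    c <- pmin(pmax(c, 1), nc)
    inside <- rep(TRUE, length(r))
  } else {
    inside <- r >= 1 & r <= nr & c >= 1 & c <= nc
    r <- r[inside]; c <- c[inside]
    if (!length(r)) return(out)
  }
  r0 <- pmin(floor(r), nr - 1L)
  c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0
  fc <- c - c0
  i00 <- r0 + (c0 - 1) * nr
  v <- img[i00]       * (1 - fr) * (1 - fc) +
       img[i00 + 1]   * fr       * (1 - fc) +
       img[i00 + nr]  * (1 - fr) * fc +
       img[i00 + nr + 1] * fr    * fc
  out[inside] <- v
  out
}

# Sample several images at the same fractional coordinates (clamp mode),
# sharing the index computation. Returns a list of numeric vectors.
interp_bilinear_multi <- function(imgs, r, c) {
  nr <- nrow(imgs[[1]]); nc <- ncol(imgs[[1]])
  r[r < 1] <- 1; r[r > nr] <- nr
  c[c < 1] <- 1; c[c > nc] <- nc
  r0 <- floor(r); r0[r0 > nr - 1L] <- nr - 1L
  c0 <- floor(c); c0[c0 > nc - 1L] <- nc - 1L
  fr <- r - r0; fc <- c - c0
  i00 <- r0 + (c0 - 1) * nr
  w00 <- (1 - fr) * (1 - fc); w10 <- fr * (1 - fc)
  w01 <- (1 - fr) * fc;       w11 <- fr * fc
  lapply(imgs, function(img) {
    img[i00] * w00 + img[i00 + 1] * w10 + img[i00 + nr] * w01 + img[i00 + nr + 1] * w11
  })
}

# Nearest-neighbour lookup, 0 outside the image.
interp_nearest <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  out <- numeric(length(r))
  ri <- round(r); ci <- round(c)
  inside <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  out[inside] <- img[ri[inside] + (ci[inside] - 1) * nr]
  out
}

# Dense 1-D Gaussian smoothing operator with renormalized borders.
# Returns an n x n matrix G such that G %*% x smooths along that axis.
gaussian_operator <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  idx <- seq_len(n)
  d <- outer(idx, idx, "-")
  g <- exp(-d^2 / (2 * sigma^2))
  g[abs(d) > ceiling(4 * sigma)] <- 0
  g / rowSums(g)
}

# Separable Gaussian blur of a matrix.
gaussian_blur <- function(img, sigma, Gr = NULL, Gc = NULL) {
  if (is.null(Gr)) Gr <- gaussian_operator(nrow(img), sigma)
  if (is.null(Gc)) Gc <- gaussian_operator(ncol(img), sigma)
  Gr %*% img %*% t(Gc)
}

# Smooth ramp from 0 to 1 over [-w, w]; used for soft phantom edges.
smoothstep <- function(x, w) {
  t <- pmin(pmax((x + w) / (2 * w), 0), 1)
  t * t * (3 - 2 * t)
}

# Largest connected component of a binary matrix (8-connectivity).
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) stop("mask has no foreground", call. = FALSE)
  tab <- tabulate(lab[lab > 0])
  (lab == which.max(tab)) * 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
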