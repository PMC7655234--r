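# Analytic 2D thorax phantom for the synthetic cine-MR generator.
#
# The phantom is a sagittal slice: a soft-edged body with an anterior chest
# wall band, a dark lung containing bright vessels and a tumour, a domed
# diaphragm and a bright abdomen. All masks are generated analytically, so
# every invariant (tumour inside sliding region inside body) holds by
# construction and no manual segmentation is emulated.

#' Default phantom configuration
#'
#' Geometry is expressed in fractions of the image extent so any shape of at
#' least 64 x 64 can be generated; defaults match a 128 x 128 slice at
#' 1.98 mm in-plane resolution (253 x 253 mm field of view).
#'
#' @param shape Image shape `(rows, cols)`; rows = SI (down = inferior),
#'   cols = AP (right = posterior).
#' @param pixel_spacing_mm Per-axis spacing in mm.
#' @param tumour_radius_mm Tumour radius; 0 gives an empty tumour mask.
#' @param edge_width_px Soft-edge width in pixels (sub-pixel edges are what
#'   the trackers rely on).
#' @param skin_edge_width_px Width of the outer body/skin boundary. The
#'   default is deliberately wider than the internal edges: the skin
#'   surrogate is meant to be the least informative signal (a shallow 3 mm
#'   excursion read off a soft boundary), emulating how poorly a chest skin
#'   signal represents internal motion on patient data.
#' @return Named list of phantom parameters.
#' @export
phantom_config <- function(shape = c(128L, 128L),
                           pixel_spacing_mm = c(1.98, 1.98),
                           tumour_radius_mm = 11,
                           edge_width_px = 0.8,
                           skin_edge_width_px = 4) {
  list(shape = as.integer(shape),
       pixel_spacing_mm = rep(as.numeric(pixel_spacing_mm), length.out = 2),
       tumour_radius_mm = tumour_radius_mm,
       edge_width_px = edge_width_px,
       skin_edge_width_px = skin_edge_width_px,
       # fractions of (rows, cols)
       body_row = c(0.03, 0.985), body_col = c(0.18, 0.92),
       chest_inner_col = 0.255,      # anterior chest wall band: skin..here
       region_row_min = 0.06,        # sliding region starts below shoulders
       region_col_max = 0.85,        # thin posterior band stays with region 0
       lung_row_min = 0.09, lung_col = c(0.30, 0.80),
       dia_apex_row = 0.52, dia_edge_drop = 0.16, dia_apex_col = 0.55,
       tumour_centre = c(0.40, 0.64),
       skin_row = 0.32,              # row at which the skin tracker looks
       vessels = cbind(row = c(0.20, 0.30, 0.38, 0.26, 0.44, 0.16),
                       col = c(0.42, 0.55, 0.47, 0.68, 0.62, 0.60),
                       r_mm = c(4.5, 3.5, 3.0, 4.0, 3.0, 2.5)),
       abdo_blobs = cbind(row = c(0.75, 0.85, 0.80),
                          col = c(0.45, 0.60, 0.72), r_mm = c(9, 7, 8)))
}

#' Generate the analytic thorax phantom
#'
#' @param config Parameter list from [phantom_config()].
#' @return A `phantom_anatomy` object: `reference_image` (intensities in
#'   `[0, 1]`), `pixel_spacing_mm`, binary `region_mask` (1 = sliding
#'   lung/mediastinum/abdomen region), `body_mask`, `tumour_mask`,
#'   `evaluation_mask`, and the `diaphragm_seed_point` / `skin_seed_point`
#'   pixel coordinates sitting on high-contrast SI / AP edges.
#' @export
make_phantom <- function(config = phantom_config()) {
  shape <- config$shape
  h <- config$pixel_spacing_mm
  if (length(shape) != 2 || any(shape < 64)) {
    stop("phantom shape must be at least 64 x 64", call. = FALSE)
  }
  if (any(h <= 0)) stop("pixel spacing must be positive", call. = FALSE)
  nr <- shape[1]; nc <- shape[2]
  r <- matrix(rep(seq_len(nr), times = nc), nr)   # row index
  c <- matrix(rep(seq_len(nc), each = nr), nr)    # col index
  w <- config$edge_width_px
  px <- function(frac, axis) frac * (if (axis == 1) nr else nc)

  # body: rounded rectangle via superellipse distance
  br <- px(config$body_row, 1); bc <- px(config$body_col, 2)
  cr0 <- mean(br); cc0 <- mean(bc)
  ar <- diff(br) / 2; ac <- diff(bc) / 2
  d_body <- (abs((r - cr0) / ar)^4 + abs((c - cc0) / ac)^4)^(1 / 4)
  body_soft <- smoothstep(1 - d_body, config$skin_edge_width_px / min(ar, ac))
  body_mask <- (d_body <= 1) * 1

  # diaphragm dome: row of the lung/abdomen interface per column
  dia_row <- px(config$dia_apex_row, 1) +
    px(config$dia_edge_drop, 1) * ((c - px(config$dia_apex_col, 2)) /
                                     (diff(px(config$lung_col, 2)) / 2))^2

  lung_c <- px(config$lung_col, 2)
  in_lung_soft <- smoothstep(r - px(config$lung_row_min, 1), w) *
    smoothstep(dia_row - r, w) *
    smoothstep(c - lung_c[1], w) * smoothstep(lung_c[2] - c, w)
  lung_mask <- (r > px(config$lung_row_min, 1) & r < dia_row &
                  c > lung_c[1] & c < lung_c[2]) * 1

  # tissue intensities
  chest_edge <- px(config$chest_inner_col, 2)
  img <- body_soft * 0.62                                    # soft tissue / wall
  abdo_soft <- smoothstep(r - dia_row, w) *
    smoothstep(c - chest_edge, w) * body_soft
  img <- img + abdo_soft * (0.13 + 0.04 * sin(r / 3.1) * sin(c / 4.3)) # abdomen
  img <- img * (1 - in_lung_soft) + in_lung_soft * 0.08              # dark lung

  blob <- function(row_f, col_f, radius_mm, value) {
    d <- sqrt(((r - px(row_f, 1)) * h[1])^2 + ((c - px(col_f, 2)) * h[2])^2)
    s <- smoothstep(radius_mm - d, w * min(h))
    img <<- img * (1 - s) + s * value
  }
  v <- config$vessels
  for (i in seq_len(nrow(v))) blob(v[i, 1], v[i, 2], v[i, 3], 0.55)
  a <- config$abdo_blobs
  for (i in seq_len(nrow(a))) blob(a[i, 1], a[i, 2], a[i, 3], 0.52)

  tum <- config$tumour_centre
  d_tum <- sqrt(((r - px(tum[1], 1)) * h[1])^2 + ((c - px(tum[2], 2)) * h[2])^2)
  tumour_mask <- (d_tum <= config$tumour_radius_mm) * 1
  if (config$tumour_radius_mm > 0) blob(tum[1], tum[2], config$tumour_radius_mm, 0.85)

  # sliding region: interior of the body, behind the chest wall band
  region_mask <- body_mask *
    (c > chest_edge) * (c < px(config$region_col_max, 2)) *
    (r > px(config$region_row_min, 1)) * 1
  tumour_mask <- tumour_mask * region_mask

  ev <- EBImage::erode(body_mask, EBImage::makeBrush(5, "disc"))
  evaluation_mask <- matrix(as.numeric(ev > 0), nr, nc)

  # tracker column: away from the tumour and vessels, on a clean lung/abdomen edge
  dia_col <- round(px(config$dia_apex_col, 2) - 0.08 * nc)
  structure(list(
    reference_image = img,
    pixel_spacing_mm = h,
    region_mask = region_mask,
    body_mask = body_mask,
    tumour_mask = tumour_mask,
    evaluation_mask = evaluation_mask,
    diaphragm_seed_point = c(round(dia_row[1, dia_col]), dia_col),
    skin_seed_point = c(round(px(config$skin_row, 1)),
                        round(cr_skin_col(d_body, px(config$skin_row, 1)))),
    config = config
  ), class = "phantom_anatomy")
}

# Anterior body boundary column at a given row (skin edge).
cr_skin_col <- function(d_body, row) {
  inside <- which(d_body[row, ] <= 1)
  min(inside)
}
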