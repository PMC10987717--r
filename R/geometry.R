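# Geometric primitives --------------------------------------------------------
#
# Everything works in physical microns on pixel centres. Erosion and dilation
# are realized as thresholds on exact Euclidean distance to the boundary
# curves rather than as discrete structuring elements: this avoids
# disk-discretization anisotropy and admits an exact brute-force oracle.

# even-odd (ray crossing) point-in-polygon test, vectorized over points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# minimum Euclidean distance from points to a polyline (closed or open),
# vectorized over points with a loop over segments
dist_to_segments <- function(px, py, vx, vy, closed = TRUE) {
  n <- length(vx)
  ends <- if (closed) c(seq_len(n)[-1], 1L) else seq_len(n)[-1]
  best <- rep(Inf, length(px))
  for (k in seq_along(ends)) {
    x1 <- vx[k]; y1 <- vy[k]; x2 <- vx[ends[k]]; y2 <- vy[ends[k]]
    dx <- x2 - x1; dy <- y2 - y1
    l2 <- dx * dx + dy * dy
    t <- if (l2 == 0) 0 else pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / l2))
    d2 <- (px - x1 - t * dx)^2 + (py - y1 - t * dy)^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# do any two non-adjacent segments of the closed polygon intersect?
polygon_is_simple <- function(vx, vy) {
  n <- length(vx)
  if (n < 3) return(FALSE)
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 2)) {
    # candidate partners: all later segments that do not share a vertex
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]
    if (!length(js)) next
    p1x <- vx[i]; p1y <- vy[i]; p2x <- vx[nxt[i]]; p2y <- vy[nxt[i]]
    q1x <- vx[js]; q1y <- vy[js]; q2x <- vx[nxt[js]]; q2y <- vy[nxt[js]]
    d1 <- (p2x - p1x) * (q1y - p1y) - (p2y - p1y) * (q1x - p1x)
    d2 <- (p2x - p1x) * (q2y - p1y) - (p2y - p1y) * (q2x - p1x)
    d3 <- (q2x - q1x) * (p1y - q1y) - (q2y - q1y) * (p1x - q1x)
    d4 <- (q2x - q1x) * (p2y - q1y) - (q2y - q1y) * (p2x - q1x)
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

#' Rasterize a closed boundary polyline onto a pixel grid
#'
#' A pixel belongs to the polygon iff its centre, at
#' `((col - 0.5), (row - 0.5)) * pixel_size_um`, lies inside the polygon by
#' the even-odd rule.
#'
#' @param boundary A closed, simple [boundary_polyline()] in microns.
#' @param grid A [pixel_grid()].
#' @return Logical matrix (`height x width`).
#' @export
#' @examples
#' sq <- boundary_polyline(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' sum(rasterize_polygon(sq, pixel_grid(12, 12, 1)))  # 100 pixels
rasterize_polygon <- function(boundary, grid) {
  stopifnot(inherits(boundary, "boundary_polyline"), inherits(grid, "pixel_grid"))
  if (!boundary$closed || length(boundary$x) < 3)
    oq_abort("rasterization needs a closed polygon with >= 3 vertices.", "geometry")
  if (!polygon_is_simple(boundary$x, boundary$y))
    oq_abort("polygon is self-intersecting; only simple polygons are supported.",
             "geometry")
  ctr <- grid_centers(grid)
  matrix(point_in_polygon(ctr$x, ctr$y, boundary$x, boundary$y),
         nrow = grid$height, ncol = grid$width)
}

# distance (um) from every pixel centre to a polyline, as a matrix
dist_raster <- function(boundary, grid) {
  ctr <- grid_centers(grid)
  matrix(dist_to_segments(ctr$x, ctr$y, boundary$x, boundary$y,
                          closed = boundary$closed),
         nrow = grid$height, ncol = grid$width)
}

# is polygon `inner` strictly inside polygon `outer`? (all vertices inside,
# no edge crossings)
polygon_inside <- function(inner, outer) {
  all(point_in_polygon(inner$x, inner$y, outer$x, outer$y)) &&
    !polygons_edges_cross(inner, outer)
}

polygons_edges_cross <- function(a, b) {
  na <- length(a$x); nb <- length(b$x)
  nxa <- c(seq_len(na)[-1], 1L); nxb <- c(seq_len(nb)[-1], 1L)
  for (i in seq_len(na)) {
    p1x <- a$x[i]; p1y <- a$y[i]; p2x <- a$x[nxa[i]]; p2y <- a$y[nxa[i]]
    q1x <- b$x; q1y <- b$y; q2x <- b$x[nxb]; q2y <- b$y[nxb]
    d1 <- (p2x - p1x) * (q1y - p1y) - (p2y - p1y) * (q1x - p1x)
    d2 <- (p2x - p1x) * (q2y - p1y) - (p2y - p1y) * (q2x - p1x)
    d3 <- (q2x - q1x) * (p1y - q1y) - (q2y - q1y) * (p1x - q1x)
    d4 <- (q2x - q1x) * (p2y - q1y) - (q2y - q1y) * (p2x - q1x)
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

# ROI construction -------------------------------------------------------------

#' Build the rosette Body mask
#'
#' The Body is the tissue between the hand-drawn outer boundary and the inner
#' luminal boundary, eroded by `erosion_um` so that neither boundary's edge
#' pixels contaminate the measurement: a pixel survives iff it lies in the
#' annulus and its centre is strictly farther than `erosion_um` (in microns)
#' from both boundary curves. With `refine = TRUE` the mask is additionally
#' intersected with the pixels at or above the Otsu threshold computed over
#' the annulus intensities, removing background pixels from the hand-drawn
#' region.
#'
#' @param outer,inner Closed [boundary_polyline()]s; `inner` strictly inside
#'   `outer`.
#' @param channel [image_channel()] supplying the grid (and the intensities
#'   for refinement).
#' @param erosion_um Erosion depth in microns (default 1.8).
#' @param refine Apply Otsu background removal within the annulus?
#' @return Logical mask with attributes `erosion_um`, `otsu_threshold`
#'   (NA unless refined) and `refine_channel`.
#' @seealso [build_ribbon_mask()], [rosette_roi()]
#' @export
build_body_mask <- function(outer, inner, channel, erosion_um = 1.8,
                            refine = FALSE) {
  stopifnot(inherits(channel, "image_channel"))
  if (erosion_um < 0) oq_abort("`erosion_um` must be >= 0.", "parameter")
  grid <- channel$grid
  out_r <- rasterize_polygon(outer, grid)
  in_r <- rasterize_polygon(inner, grid)
  if (!polygon_inside(inner, outer))
    oq_abort("inner boundary must lie strictly inside the outer boundary.",
             "geometry")
  annulus <- out_r & !in_r
  body <- annulus
  if (erosion_um > 0) {
    d <- pmin(dist_raster(outer, grid), dist_raster(inner, grid))
    body <- annulus & (d > erosion_um)
  }
  thr <- NA_real_
  if (refine) {
    thr <- otsu_threshold(channel$data[annulus])
    body <- body & (channel$data >= thr)
  }
  if (!any(body))
    warn("body mask is empty after erosion/refinement; returning empty mask.",
         class = "oq_warning_degenerate")
  structure(body, erosion_um = erosion_um, otsu_threshold = thr,
            refine_channel = if (refine) channel$channel else NA_character_)
}

#' Build the rosette Ribbon mask
#'
#' The Ribbon is the thin apical band of elevated signal hugging the lumen: the
#' inner luminal boundary line dilated by `dilation_um`, i.e. all pixels whose
#' centres lie within `dilation_um` microns of the inner boundary curve
#' (both sides of the line). The `<=` tie-break here, against the strict `>`
#' of [build_body_mask()], guarantees Body and Ribbon are disjoint when
#' `dilation_um == erosion_um`.
#'
#' @inheritParams build_body_mask
#' @param dilation_um Dilation radius in microns (default 1.8, approximately
#'   the full ribbon thickness).
#' @return Logical mask with attributes `dilation_um`, `otsu_threshold`,
#'   `refine_channel`.
#' @export
build_ribbon_mask <- function(inner, channel, dilation_um = 1.8,
                              refine = FALSE) {
  stopifnot(inherits(channel, "image_channel"))
  if (dilation_um < 0) oq_abort("`dilation_um` must be >= 0.", "parameter")
  grid <- channel$grid
  band <- dist_raster(inner, grid) <= dilation_um
  thr <- NA_real_
  if (refine) {
    if (!any(band))
      oq_abort("ribbon band is empty; cannot refine.", "degenerate")
    thr <- otsu_threshold(channel$data[band])
    band <- band & (channel$data >= thr)
  }
  structure(band, dilation_um = dilation_um, otsu_threshold = thr,
            refine_channel = if (refine) channel$channel else NA_character_)
}

#' Assemble a rosette ROI from its two boundaries
#'
#' Convenience constructor running [build_body_mask()] and
#' [build_ribbon_mask()] with shared settings.
#'
#' @inheritParams build_body_mask
#' @param dilation_um Ribbon dilation radius in microns.
#' @return A `rosette_roi` object: list with `body`, `ribbon`, `grid` and the
#'   parameters used.
#' @export
rosette_roi <- function(outer, inner, channel, erosion_um = 1.8,
                        dilation_um = 1.8, refine = FALSE) {
  body <- build_body_mask(outer, inner, channel, erosion_um, refine)
  ribbon <- build_ribbon_mask(inner, channel, dilation_um, refine)
  structure(
    list(body = body, ribbon = ribbon, grid = channel$grid,
         erosion_um = erosion_um, dilation_um = dilation_um,
         refine = refine,
         otsu_threshold = c(body = attr(body, "otsu_threshold"),
                            ribbon = attr(ribbon, "otsu_threshold")),
         refine_channel = attr(body, "refine_channel")),
    class = "rosette_roi"
  )
}

#' @export
print.rosette_roi <- function(x, ...) {
  cat(sprintf(
    "<rosette_roi> body %d px (erosion %g um), ribbon %d px (dilation %g um)%s\n",
    sum(x$body), x$erosion_um, sum(x$ribbon), x$dilation_um,
    if (x$refine) sprintf(", Otsu-refined on '%s'", x$refine_channel) else ""))
  invisible(x)
}

#' Rosette area and aspect ratio
#'
#' Area is the summed pixel count of Body union Ribbon times the pixel area
#' (the lumen interior is not included). Aspect ratio is the major/minor axis
#' length ratio of the ellipse with the same normalized second central moments
#' as the hole-filled union region — the filled outline captures the rosette's
#' overall shape rather than the annulus itself.
#'
#' @param roi A [rosette_roi()].
#' @param grid Optional [pixel_grid()]; defaults to the ROI's grid.
#' @return A tibble with columns `area_um2` and `aspect_ratio` (>= 1).
#' @export
rosette_morphometrics <- function(roi, grid = roi$grid) {
  u <- roi$body | roi$ribbon
  if (!any(u)) oq_abort("empty rosette ROI; no morphometrics.", "degenerate")
  area <- sum(u) * grid$pixel_size_um^2
  filled <- EBImage::fillHull(matrix(as.integer(u), nrow(u), ncol(u))) > 0
  # axis lengths of the equal-second-moment ellipse, from the pixel-coordinate
  # covariance (eigenvalues scale both axes identically, so the ratio is
  # independent of the ellipse normalisation)
  idx <- which(filled, arr.ind = TRUE)
  xy <- cbind(idx[, 2], idx[, 1]) * grid$pixel_size_um
  if (nrow(xy) < 2) return(tibble(area_um2 = area, aspect_ratio = 1))
  cv <- stats::cov(xy) * (nrow(xy) - 1) / nrow(xy)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ar <- if (ev[2] <= 0) Inf else sqrt(ev[1] / ev[2])
  tibble(area_um2 = area, aspect_ratio = max(1, ar))
}

#' Measure one rosette: ROI intensities plus morphometrics
#'
#' The full per-rosette record behind the group comparisons: mean channel
#' intensity over Body and Ribbon, rosette area and aspect ratio.
#'
#' @param channel [image_channel()] to quantify (e.g. beta-catenin).
#' @param outer,inner Closed boundary polylines.
#' @param rosette_id,group Identifier and condition label carried through to
#'   the output row.
#' @inheritParams rosette_roi
#' @return One-row tibble: `rosette_id`, `group`, `mean_body`, `mean_ribbon`,
#'   `area_um2`, `aspect_ratio`.
#' @export
measure_rosette <- function(channel, outer, inner, rosette_id = "rosette",
                            group = "group", erosion_um = 1.8,
                            dilation_um = 1.8, refine = FALSE) {
  roi <- rosette_roi(outer, inner, channel, erosion_um, dilation_um, refine)
  morpho <- rosette_morphometrics(roi)
  tibble(
    rosette_id = rosette_id, group = group,
    mean_body = mean_roi_intensity(channel, roi$body),
    mean_ribbon = mean_roi_intensity(channel, roi$ribbon),
    area_um2 = morpho$area_um2, aspect_ratio = morpho$aspect_ratio
  )
}
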