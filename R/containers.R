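#' Calibrated pixel grid
#'
#' A `pixel_grid` records the raster geometry shared by an image and any mask
#' derived from it: width and height in pixels plus the physical pixel size in
#' microns. All geometry in the package is computed in microns; pixel centres
#' sit at `(i + 0.5, j + 0.5) * pixel_size_um` with 0-based indices, x running
#' along columns and y downward along rows (image convention).
#'
#' @param width,height Raster dimensions in pixels (>= 1).
#' @param pixel_size_um Physical pixel edge length in microns (> 0).
#' @return An object of class `pixel_grid`.
#' @export
#' @examples
#' pixel_grid(256, 256, 0.25)
pixel_grid <- function(width, height, pixel_size_um) {
  stopifnot(length(width) == 1, length(height) == 1, length(pixel_size_um) == 1)
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    oq_abort("`pixel_size_um` must be a positive finite number.", "parameter")
  if (width < 1 || height < 1)
    oq_abort("grid dimensions must be >= 1 pixel.", "parameter")
  structure(
    list(width = as.integer(width), height = as.integer(height),
         pixel_size_um = as.numeric(pixel_size_um)),
    class = "pixel_grid"
  )
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("<pixel_grid> %d x %d px @ %g um/px (%g x %g um)\n",
              x$width, x$height, x$pixel_size_um,
              x$width * x$pixel_size_um, x$height * x$pixel_size_um))
  invisible(x)
}

# micron coordinates of every pixel centre, as vectors aligned with
# as.vector(matrix) (column-major: rows fastest)
grid_centers <- function(grid) {
  px <- grid$pixel_size_um
  row <- rep(seq_len(grid$height), times = grid$width)
  col <- rep(seq_len(grid$width), each = grid$height)
  list(x = (col - 0.5) * px, y = (row - 0.5) * px)
}

#' Single-channel calibrated intensity image
#'
#' Wraps a numeric matrix of non-negative intensities (arbitrary units, AU)
#' together with its [pixel_grid()] calibration and a channel name. The matrix
#' is indexed `[row, col]` = `[y, x]`.
#'
#' @param data Numeric matrix of finite, non-negative intensities.
#' @param pixel_size_um Pixel size in microns, or a [pixel_grid()].
#' @param channel Channel name (e.g. `"beta-catenin"`).
#' @return An `image_channel` object.
#' @export
image_channel <- function(data, pixel_size_um, channel = "") {
  if (!is.matrix(data) || !is.numeric(data))
    oq_abort("`data` must be a numeric matrix.", "parameter")
  if (any(!is.finite(data)) || any(data < 0))
    oq_abort("intensities must be finite and non-negative.", "parameter")
  grid <- if (inherits(pixel_size_um, "pixel_grid")) pixel_size_um
          else pixel_grid(ncol(data), nrow(data), pixel_size_um)
  if (grid$width != ncol(data) || grid$height != nrow(data))
    oq_abort("grid dimensions do not match the data matrix.", "parameter")
  structure(list(data = data, grid = grid, channel = as.character(channel)),
            class = "image_channel")
}

#' @export
print.image_channel <- function(x, ...) {
  cat(sprintf("<image_channel> '%s' %d x %d px @ %g um/px, range [%g, %g] AU\n",
              x$channel, x$grid$width, x$grid$height, x$grid$pixel_size_um,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Boundary polyline in micron coordinates
#'
#' An ordered vertex list describing a hand-drawn rosette boundary (outer
#' tissue boundary or inner luminal boundary). Closed polylines are treated as
#' simple polygons; self-intersecting polygons are rejected by the raster
#' operations.
#'
#' @param x,y Vertex coordinates in microns (equal length), or `x` may be a
#'   two-column matrix/data frame.
#' @param closed Logical; closed polylines (>= 3 vertices) can be rasterized.
#' @return A `boundary_polyline` object.
#' @export
boundary_polyline <- function(x, y = NULL, closed = TRUE) {
  if (is.null(y)) {
    m <- as.matrix(x)
    stopifnot(ncol(m) == 2)
    x <- m[, 1]; y <- m[, 2]
  }
  if (length(x) != length(y) || length(x) < 2)
    oq_abort("a polyline needs >= 2 (x, y) vertices.", "geometry")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    oq_abort("vertex coordinates must be finite.", "geometry")
  # drop a duplicated closing vertex so the vertex list is open-form
  n <- length(x)
  if (closed && n > 2 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]
  }
  structure(list(x = as.numeric(x), y = as.numeric(y), closed = isTRUE(closed)),
            class = "boundary_polyline")
}

#' @export
print.boundary_polyline <- function(x, ...) {
  cat(sprintf("<boundary_polyline> %d vertices, %s\n", length(x$x),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

#' Multi-channel 3D volume stack
#'
#' Holds named 3D intensity arrays sharing one shape, with anisotropic voxel
#' size in microns. The canonical channel roles for colocalization reports are
#' `target` (e.g. beta-catenin), `nuclear` (DAPI) and `neuronal` (NeuN).
#' 2D images are accepted as single-slice volumes.
#'
#' @param channels Named list of numeric 3D arrays (or matrices).
#' @param voxel_size_um Length-3 numeric, voxel edge lengths in microns.
#' @return A `volume_stack` object.
#' @export
volume_stack <- function(channels, voxel_size_um = c(1, 1, 1)) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    oq_abort("`channels` must be a named list of arrays.", "parameter")
  channels <- lapply(channels, function(a) {
    if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
    if (length(dim(a)) != 3) oq_abort("channels must be 2D or 3D arrays.", "parameter")
    if (any(!is.finite(a)) || any(a < 0))
      oq_abort("intensities must be finite and non-negative.", "parameter")
    a
  })
  dims <- lapply(channels, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    oq_abort("all channels must share one shape.", "parameter")
  stopifnot(length(voxel_size_um) == 3, all(voxel_size_um > 0))
  structure(list(channels = channels, voxel_size_um = as.numeric(voxel_size_um)),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<volume_stack> %s voxels, %s; channels: %s\n",
              paste(d, collapse = " x "),
              paste(x$voxel_size_um, collapse = " x "),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Gene-by-cell count matrix
#'
#' A sparse genes x cells matrix of non-negative integer counts plus the
#' metadata the expression screen needs: a sample label, optional per-cell
#' cluster labels (clustering is an input here, produced by upstream tools),
#' and the set of mitochondrial gene ids used for `percent.mito`.
#'
#' @param counts genes x cells matrix (dense or `Matrix` sparse) of counts.
#' @param sample Sample label.
#' @param clusters Optional per-cell cluster labels (length = ncol).
#' @param mito_genes Character vector of mitochondrial gene ids (subset of
#'   rownames).
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, sample = "sample", clusters = NULL,
                         mito_genes = character()) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    oq_abort("counts must carry gene rownames and cell colnames.", "parameter")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    oq_abort("gene and cell ids must be unique.", "parameter")
  v <- counts@x
  if (any(v < 0) || any(v != round(v)))
    oq_abort("counts must be non-negative integers.", "parameter")
  if (!all(mito_genes %in% rownames(counts)))
    oq_abort("unknown mitochondrial gene id(s).", "parameter")
  if (!is.null(clusters)) {
    if (length(clusters) != ncol(counts))
      oq_abort("`clusters` must label every cell.", "parameter")
    clusters <- as.character(clusters)
    names(clusters) <- colnames(counts)
  }
  structure(list(counts = counts, sample = as.character(sample),
                 clusters = clusters, mito_genes = as.character(mito_genes)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> '%s': %d genes x %d cells (%d mito genes%s)\n",
              x$sample, nrow(x$counts), ncol(x$counts), length(x$mito_genes),
              if (is.null(x$clusters)) ""
              else sprintf(", %d clusters", length(unique(x$clusters)))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Planted ground truth attached to every synthetic scene; the test oracle.
scene_truth <- function(..., seed) {
  structure(c(list(...), list(seed = as.integer(seed))), class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("<scene_truth> fields:", paste(setdiff(names(x), "seed"), collapse = ", "),
      sprintf("(seed %d)\n", x$seed))
  invisible(x)
}
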