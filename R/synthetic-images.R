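# Synthetic imaging scenes -----------------------------------------------------
#
# Seeded generators planting known ground truth for every imaging stage.
# The noise model is additive Gaussian clipped at zero, so that noiseless
# scenes reproduce every planted mean exactly; regions are painted from the
# same polygonal truth boundaries that are handed to the ROI stage, making the
# planted-truth consistency property exact rather than approximate.

# dense polygonal approximation of a (rotated) ellipse, in microns
ellipse_polyline <- function(center, semiaxes, rotation = 0, n_vertices = 128) {
  th <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  x0 <- semiaxes[1] * cos(th)
  y0 <- semiaxes[2] * sin(th)
  boundary_polyline(
    center[1] + x0 * cos(rotation) - y0 * sin(rotation),
    center[2] + x0 * sin(rotation) + y0 * cos(rotation)
  )
}

#' Parameters of a synthetic neural-rosette scene
#'
#' Describes one rosette: an elliptical lumen surrounded by a thin apical
#' ribbon of elevated signal and a tissue body at lower intensity, over a
#' background with optional linear illumination gradient and additive Gaussian
#' noise. Defaults depict a mid-size rosette in a 64 x 64 um field at
#' 0.25 um/px, with ribbon signal three times the body signal — the apical
#' enrichment pattern this scene emulates.
#'
#' @param size Image size in pixels, `c(width, height)`.
#' @param pixel_size_um Pixel size in microns.
#' @param outer_semiaxes,lumen_semiaxes Ellipse semi-axes in microns; the
#'   lumen must fit strictly inside the outer boundary.
#' @param center Rosette centre in microns.
#' @param lumen_center Lumen centre in microns (defaults to `center`; the
#'   lumen must stay strictly inside the outer boundary).
#' @param rotation Rotation in radians.
#' @param body_mean,ribbon_mean,background_mean Region intensities (AU).
#' @param ribbon_halfwidth_um Half-thickness of the apical ribbon band in
#'   microns (painted both sides of the luminal boundary line).
#' @param illumination_gradient_amplitude Linear left-to-right illumination
#'   ramp amplitude, AU per image width.
#' @param noise_sigma Additive Gaussian noise sd (AU), clipped at 0.
#' @param n_vertices Vertices of the polygonal truth boundaries (>= 128).
#' @param seed Integer seed.
#' @return A `rosette_scene_params` list.
#' @export
rosette_scene_params <- function(size = c(256, 256), pixel_size_um = 0.25,
                                 outer_semiaxes = c(25, 20),
                                 lumen_semiaxes = c(8, 6),
                                 center = size * pixel_size_um / 2,
                                 lumen_center = center,
                                 rotation = 0,
                                 body_mean = 100, ribbon_mean = 300,
                                 ribbon_halfwidth_um = 1.8,
                                 background_mean = 20,
                                 illumination_gradient_amplitude = 0,
                                 noise_sigma = 10,
                                 n_vertices = 128, seed = 1L) {
  p <- list(size = as.integer(size), pixel_size_um = pixel_size_um,
            outer_semiaxes = outer_semiaxes, lumen_semiaxes = lumen_semiaxes,
            center = center, lumen_center = lumen_center,
            rotation = rotation, body_mean = body_mean,
            ribbon_mean = ribbon_mean, ribbon_halfwidth_um = ribbon_halfwidth_um,
            background_mean = background_mean,
            illumination_gradient_amplitude = illumination_gradient_amplitude,
            noise_sigma = noise_sigma, n_vertices = as.integer(n_vertices),
            seed = as.integer(seed))
  if (any(p$lumen_semiaxes >= p$outer_semiaxes))
    oq_abort("lumen semi-axes must be strictly smaller than the outer semi-axes.",
             "parameter")
  if (p$ribbon_halfwidth_um <= 0)
    oq_abort("`ribbon_halfwidth_um` must be > 0.", "parameter")
  if (any(c(p$body_mean, p$ribbon_mean, p$background_mean) < 0) ||
      p$noise_sigma < 0)
    oq_abort("intensities and noise sd must be >= 0.", "parameter")
  if (p$n_vertices < 128)
    oq_abort("truth boundaries need >= 128 vertices.", "parameter")
  structure(p, class = "rosette_scene_params")
}

# region layout is deterministic in the geometric parameters; cache it so that
# repeated generation (power studies) only redraws intensities and noise
rosette_scene_geometry <- function(p) {
  key <- paste(c(p$size, p$pixel_size_um, p$outer_semiaxes, p$lumen_semiaxes,
                 p$center, p$lumen_center, p$rotation, p$ribbon_halfwidth_um,
                 p$n_vertices),
               collapse = "|")
  hit <- the$rosette_geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  grid <- pixel_grid(p$size[1], p$size[2], p$pixel_size_um)
  outer <- ellipse_polyline(p$center, p$outer_semiaxes, p$rotation, p$n_vertices)
  inner <- ellipse_polyline(p$lumen_center, p$lumen_semiaxes, p$rotation,
                            p$n_vertices)
  if (!polygon_inside(inner, outer))
    oq_abort("lumen boundary is not strictly inside the outer boundary.",
             "parameter")
  outer_in <- rasterize_polygon(outer, grid)
  lumen_in <- rasterize_polygon(inner, grid)
  ribbon <- dist_raster(inner, grid) <= p$ribbon_halfwidth_um
  body <- outer_in & !lumen_in & !ribbon
  geom <- list(grid = grid, outer = outer, inner = inner,
               ribbon = ribbon, body = body)
  if (is.null(the$rosette_geom_cache)) the$rosette_geom_cache <- list()
  if (length(the$rosette_geom_cache) > 32) the$rosette_geom_cache <- list()
  the$rosette_geom_cache[[key]] <- geom
  geom
}

#' Generate a synthetic rosette scene with known ground truth
#'
#' Composites background + illumination gradient + body/ribbon region
#' intensities + clipped Gaussian noise, and returns the image together with
#' the planted truth: the polygonal outer/inner boundaries (the stand-in for
#' hand-drawing) and the planted per-region means. In the noiseless,
#' gradient-free case the mean over the true ribbon band equals `ribbon_mean`
#' exactly.
#'
#' @param params A [rosette_scene_params()].
#' @return List with `image` ([image_channel()]) and `truth` (`scene_truth`
#'   carrying `outer`, `inner`, `region_means`, `ribbon_mask`, `body_mask`).
#' @export
#' @examples
#' sc <- make_rosette_scene(rosette_scene_params(noise_sigma = 0))
#' mean_roi_intensity(sc$image, sc$truth$ribbon_mask)  # exactly 300
make_rosette_scene <- function(params) {
  stopifnot(inherits(params, "rosette_scene_params"))
  p <- params
  g <- rosette_scene_geometry(p)
  w_um <- p$size[1] * p$pixel_size_um
  ctr <- grid_centers(g$grid)
  img <- matrix(p$background_mean +
                  p$illumination_gradient_amplitude * (ctr$x / w_um - 0.5),
                nrow = p$size[2], ncol = p$size[1])
  img[g$body] <- p$body_mean +
    p$illumination_gradient_amplitude * (ctr$x[as.vector(g$body)] / w_um - 0.5)
  img[g$ribbon] <- p$ribbon_mean +
    p$illumination_gradient_amplitude * (ctr$x[as.vector(g$ribbon)] / w_um - 0.5)
  if (p$noise_sigma > 0) {
    img <- withr::with_seed(p$seed,
      img + matrix(rnorm(length(img), 0, p$noise_sigma), nrow(img)))
    img <- pmax(img, 0)
  }
  list(
    image = image_channel(img, g$grid, "rosette"),
    truth = scene_truth(
      outer = g$outer, inner = g$inner,
      region_means = c(body = p$body_mean, ribbon = p$ribbon_mean,
                       background = p$background_mean),
      ribbon_mask = g$ribbon, body_mask = g$body,
      ribbon_halfwidth_um = p$ribbon_halfwidth_um,
      seed = p$seed
    )
  )
}

#' Generate a synthetic punctate marker field
#'
#' Emulates a pTau S396 / Reelin-style field: an affine background plane plus
#' disk-shaped puncta of fixed amplitude, plus clipped Gaussian noise. Puncta
#' are placed uniformly at random, kept clear of the image border, and
#' non-overlapping so the planted foreground amplitude is unambiguous;
#' placement is retried and errors after 100 consecutive failures.
#'
#' @param size Image size in pixels, `c(width, height)`.
#' @param pixel_size_um Pixel size in microns.
#' @param n_puncta Number of puncta.
#' @param punctum_radius_um Punctum disk radius in microns (must be much
#'   smaller than the 54 um top-hat structuring radius used downstream).
#' @param punctum_amp Punctum amplitude above background (AU).
#' @param background_plane_coeffs `c(a, bx, by)`: plane
#'   `a + bx * x_um + by * y_um`.
#' @param noise_sigma Additive Gaussian noise sd (AU), clipped at 0.
#' @param seed Integer seed.
#' @return List with `image` and `truth` (centres in um, `amplitude`,
#'   `foreground_mean` = planted amplitude, `punctum_mask`).
#' @export
make_marker_field <- function(size = c(256, 256), pixel_size_um = 1,
                              n_puncta = 30, punctum_radius_um = 5,
                              punctum_amp = 200,
                              background_plane_coeffs = c(50, 0, 0),
                              noise_sigma = 0, seed = 1L) {
  stopifnot(n_puncta >= 0, punctum_radius_um > 0, punctum_amp >= 0,
            length(background_plane_coeffs) == 3, noise_sigma >= 0)
  grid <- pixel_grid(size[1], size[2], pixel_size_um)
  ctr <- grid_centers(grid)
  a <- background_plane_coeffs
  img <- matrix(a[1] + a[2] * ctr$x + a[3] * ctr$y, nrow = size[2], ncol = size[1])
  if (min(img) < 0)
    oq_abort("background plane dips below zero within the field.", "parameter")
  w_um <- size[1] * pixel_size_um; h_um <- size[2] * pixel_size_um
  margin <- punctum_radius_um + pixel_size_um
  if (n_puncta > 0 && (w_um <= 2 * margin || h_um <= 2 * margin))
    oq_abort("field too small for the requested punctum radius.", "parameter")
  centers <- matrix(numeric(0), 0, 2)
  punctum_mask <- matrix(FALSE, size[2], size[1])
  withr::with_seed(seed, {
    fails <- 0
    while (nrow(centers) < n_puncta) {
      cand <- c(runif(1, margin, w_um - margin), runif(1, margin, h_um - margin))
      ok <- !nrow(centers) ||
        all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >
              (2 * punctum_radius_um + pixel_size_um)^2)
      if (ok) {
        centers <- rbind(centers, cand)
        fails <- 0
      } else {
        fails <- fails + 1
        if (fails >= 100)
          oq_abort("could not place non-overlapping puncta after 100 retries.",
                   "parameter")
      }
    }
    for (i in seq_len(nrow(centers))) {
      inside <- (ctr$x - centers[i, 1])^2 + (ctr$y - centers[i, 2])^2 <=
        punctum_radius_um^2
      img[inside] <- img[inside] + punctum_amp
      punctum_mask <- punctum_mask | matrix(inside, size[2], size[1])
    }
    if (noise_sigma > 0)
      img <- pmax(img + matrix(rnorm(length(img), 0, noise_sigma), nrow(img)), 0)
  })
  list(
    image = image_channel(img, grid, "marker"),
    truth = scene_truth(
      centers_um = centers, amplitude = punctum_amp,
      foreground_mean = punctum_amp, punctum_mask = punctum_mask,
      plane_coeffs = a, seed = seed
    )
  )
}

# one random sphere support inside the volume, as voxel indices
sphere_voxels <- function(dims, center, radius) {
  lo <- pmax(1, floor(center - radius)); hi <- pmin(dims, ceiling(center + radius))
  gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
  d2 <- outer(outer((gx - center[1])^2, (gy - center[2])^2, `+`),
              (gz - center[3])^2, `+`)
  idx <- which(d2 <= radius^2, arr.ind = TRUE)
  cbind(gx[idx[, 1]], gy[idx[, 2]], gz[idx[, 3]])
}

#' Generate a synthetic three-channel colocalization stack
#'
#' Builds a `target` channel as a union of random spheres, then constructs
#' `nuclear` and `neuronal` channels whose supra-threshold supports overlap
#' the target support by prescribed fractions (of the target's volume), by
#' taking an axial sweep of exactly `round(f * |target|)` target voxels plus
#' extra spheres placed disjoint from the target. Channels are painted
#' `fg`/`bg` with optional clipped Gaussian noise; in the noiseless case Otsu
#' thresholding recovers every support exactly.
#'
#' @param shape Volume shape in voxels, `c(nx, ny, nz)`.
#' @param voxel_size_um Length-3 voxel size in microns.
#' @param overlap Named fractions in `[0, 1]`:
#'   `c(nuclear = f1, neuronal = f2)`.
#' @param n_blobs Spheres composing the target support.
#' @param blob_radius_vox Sphere radius in voxels.
#' @param fg,bg Foreground/background intensity (AU).
#' @param noise_sigma Additive Gaussian noise sd (AU), clipped at 0.
#' @param seed Integer seed.
#' @return List with `stack` ([volume_stack()]) and `truth` (per-channel
#'   logical supports and exact planted fractions).
#' @export
make_coloc_stack <- function(shape = c(64, 64, 64), voxel_size_um = c(0.5, 0.5, 1),
                             overlap = c(nuclear = 0.5, neuronal = 0.25),
                             n_blobs = 8, blob_radius_vox = 6,
                             fg = 200, bg = 10, noise_sigma = 0, seed = 1L) {
  stopifnot(all(overlap >= 0), all(overlap <= 1),
            all(c("nuclear", "neuronal") %in% names(overlap)))
  dims <- as.integer(shape)
  withr::with_seed(seed, {
    sup <- array(FALSE, dims)
    centers <- matrix(NA_real_, n_blobs, 3)
    for (i in seq_len(n_blobs)) {
      centers[i, ] <- runif(3, blob_radius_vox + 1, dims - blob_radius_vox)
      vox <- sphere_voxels(dims, centers[i, ], blob_radius_vox)
      sup[vox] <- TRUE
    }
    a_idx <- which(sup)
    if (!length(a_idx)) oq_abort("target support is empty.", "degenerate")
    # axial sweep order: column-major linear index is already a (x,y,z) sweep
    a_ord <- sort(a_idx)
    supports <- list(target = sup)
    truth_frac <- c()
    for (ch in c("nuclear", "neuronal")) {
      f <- overlap[[ch]]
      k <- round(f * length(a_ord))
      s <- array(FALSE, dims)
      if (k > 0) s[a_ord[seq_len(k)]] <- TRUE
      if (f < 1) {
        placed <- 0; fails <- 0
        while (placed < 2) {
          cc <- runif(3, blob_radius_vox + 1, dims - blob_radius_vox)
          vox <- sphere_voxels(dims, cc, blob_radius_vox)
          lin <- vox[, 1] + dims[1] * (vox[, 2] - 1) + dims[1] * dims[2] * (vox[, 3] - 1)
          if (!any(sup[lin])) {
            s[lin] <- TRUE; placed <- placed + 1
          } else {
            fails <- fails + 1
            if (fails >= 100)
              oq_abort("cannot place off-target spheres: geometry infeasible.",
                       "parameter")
          }
        }
      }
      supports[[ch]] <- s
      truth_frac[ch] <- k / length(a_ord)
    }
    channels <- lapply(supports, function(s) {
      v <- array(bg, dims); v[s] <- fg
      if (noise_sigma > 0) v <- pmax(v + array(rnorm(length(v), 0, noise_sigma), dims), 0)
      v
    })
  })
  list(
    stack = volume_stack(channels, voxel_size_um),
    truth = scene_truth(supports = supports, overlap_fractions = truth_frac,
                        requested_overlap = overlap, seed = seed)
  )
}
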