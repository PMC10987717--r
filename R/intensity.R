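# Intensity quantification ----------------------------------------------------

#' Otsu threshold on a 256-bin histogram
#'
#' Picks the threshold maximizing the between-class variance of the intensity
#' histogram. Works on any finite numeric values (an image, or the pixels of a
#' geometric region), binning over `[min, max]`. The returned threshold is the
#' bin edge separating the two classes, so foreground selection is
#' `values >= threshold` (ties go to foreground).
#'
#' @param values Numeric vector with >= 2 distinct values.
#' @param levels Number of histogram bins (default 256).
#' @return The threshold (same units as `values`).
#' @export
otsu_threshold <- function(values, levels = 256) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (!length(values) || rng[1] == rng[2])
    oq_abort("no foreground separable: values are constant.", "degenerate")
  bin <- pmin(levels, floor((values - rng[1]) / (rng[2] - rng[1]) * levels) + 1L)
  counts <- tabulate(bin, nbins = levels)
  p <- counts / sum(counts)
  mids <- rng[1] + (seq_len(levels) - 0.5) * (rng[2] - rng[1]) / levels
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[levels]
  k <- seq_len(levels - 1)
  w1 <- 1 - w0[k]
  sigma2b <- ifelse(w0[k] > 0 & w1 > 0,
                    (mu_t * w0[k] - mu0[k])^2 / (w0[k] * w1), 0)
  kstar <- which.max(sigma2b)   # first maximum (standard lower-bin convention)
  rng[1] + kstar * (rng[2] - rng[1]) / levels
}

#' Mean raw intensity over a mask
#'
#' @param channel An [image_channel()].
#' @param mask Logical matrix matching the channel shape.
#' @return Arithmetic mean (AU) of the raw intensities at mask pixels.
#' @export
mean_roi_intensity <- function(channel, mask) {
  stopifnot(inherits(channel, "image_channel"))
  if (!identical(dim(mask), dim(channel$data)))
    oq_abort("mask and channel shapes differ.", "parameter")
  if (!any(mask)) oq_abort("mask is empty.", "degenerate")
  mean(channel$data[mask])
}

# disk structuring element: pixels whose centres lie within `radius_px`
# (pixel-centre distance, radius rounded by the caller)
disk_kernel <- function(radius_px) {
  r <- as.integer(radius_px)
  d <- 2L * r + 1L
  off <- seq_len(d) - r - 1L
  k <- outer(off, off, function(i, j) i * i + j * j) <= radius_px^2
  matrix(as.numeric(k), d, d)
}

#' Top-hat background subtraction
#'
#' White top-hat: the image minus its grayscale morphological opening with a
#' large disk (default 54 um radius), removing smooth non-uniform background
#' illumination while preserving features smaller than the disk. The disk
#' radius is `round(radius_um / pixel_size_um)` pixels and the image is
#' replicate-padded by that radius before the opening so border pixels are not
#' attenuated.
#'
#' @param channel An [image_channel()].
#' @param radius_um Structuring-disk radius in microns (default 54).
#' @return An [image_channel()] of the same shape, everywhere >= 0.
#' @export
tophat_background_subtract <- function(channel, radius_um = 54) {
  stopifnot(inherits(channel, "image_channel"))
  if (radius_um <= 0) oq_abort("`radius_um` must be > 0.", "parameter")
  r <- round(radius_um / channel$grid$pixel_size_um)
  if (r < 1)
    oq_abort("pixel size too coarse: structuring disk is < 1 px.", "parameter")
  x <- channel$data
  mx <- max(x)
  if (mx == 0) {
    out <- x                       # constant zero image: top-hat is zero
  } else {
    # EBImage grayscale morphology operates on [0, 1]; rescale, pad, open, crop
    pr <- c(rep(1L, r), seq_len(nrow(x)), rep(nrow(x), r))
    pc <- c(rep(1L, r), seq_len(ncol(x)), rep(ncol(x), r))
    padded <- x[pr, pc] / mx
    op <- EBImage::opening(padded, disk_kernel(r))
    op <- op[(r + 1):(r + nrow(x)), (r + 1):(r + ncol(x))] * mx
    out <- pmax(x - op, 0)
  }
  image_channel(out, channel$grid, channel$channel)
}

#' Otsu foreground mean of a channel
#'
#' Finds the foreground of a (typically background-subtracted) marker channel
#' with Otsu's method on the full image and reports the mean intensity over
#' the foreground pixels.
#'
#' @param channel An [image_channel()] with >= 2 distinct values.
#' @param tophat_radius_um Recorded provenance only (radius used upstream, or
#'   `NA`).
#' @return One-row tibble: `otsu_threshold`, `mean_foreground`,
#'   `foreground_fraction`, `tophat_radius_um`.
#' @export
foreground_mean <- function(channel, tophat_radius_um = NA_real_) {
  stopifnot(inherits(channel, "image_channel"))
  thr <- otsu_threshold(channel$data)
  fg <- channel$data >= thr
  tibble(
    otsu_threshold = thr,
    mean_foreground = mean(channel$data[fg]),
    foreground_fraction = mean(fg),
    tophat_radius_um = tophat_radius_um
  )
}

#' Quantify a punctate marker channel
#'
#' The full marker chain in the stated order: top-hat background subtraction
#' with a 54 um disk, then Otsu foreground selection and foreground mean.
#' Used for punctate markers such as pTau S396 and Reelin.
#'
#' @inheritParams tophat_background_subtract
#' @return One-row tibble as [foreground_mean()].
#' @export
quantify_marker <- function(channel, radius_um = 54) {
  bg <- tophat_background_subtract(channel, radius_um)
  foreground_mean(bg, tophat_radius_um = radius_um)
}
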