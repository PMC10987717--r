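# Independent brute-force oracles used across the suite. These deliberately
# take the slow, per-pixel route so they share no code path with the package.

# scalar even-odd test, looping edges for one point
oracle_point_in_poly <- function(x, y, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[j] > y) != (vy[i] > y)) {
      xint <- (vx[i] - vx[j]) * (y - vy[j]) / (vy[i] - vy[j]) + vx[j]
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# scalar min distance from a point to a closed polyline
oracle_dist_to_poly <- function(x, y, vx, vy) {
  n <- length(vx)
  best <- Inf
  j <- n
  for (i in seq_len(n)) {
    dx <- vx[i] - vx[j]; dy <- vy[i] - vy[j]
    l2 <- dx * dx + dy * dy
    t <- if (l2 == 0) 0 else max(0, min(1, ((x - vx[j]) * dx + (y - vy[j]) * dy) / l2))
    d2 <- (x - vx[j] - t * dx)^2 + (y - vy[j] - t * dy)^2
    if (d2 < best) best <- d2
    j <- i
  }
  sqrt(best)
}

# per-pixel brute-force Body and Ribbon masks
oracle_masks <- function(outer, inner, grid, erosion_um, dilation_um) {
  px <- grid$pixel_size_um
  body <- matrix(FALSE, grid$height, grid$width)
  ribbon <- matrix(FALSE, grid$height, grid$width)
  for (col in seq_len(grid$width)) {
    x <- (col - 0.5) * px
    for (row in seq_len(grid$height)) {
      y <- (row - 0.5) * px
      d_in <- oracle_dist_to_poly(x, y, inner$x, inner$y)
      ribbon[row, col] <- d_in <= dilation_um
      in_ann <- oracle_point_in_poly(x, y, outer$x, outer$y) &&
        !oracle_point_in_poly(x, y, inner$x, inner$y)
      if (in_ann) {
        d_out <- oracle_dist_to_poly(x, y, outer$x, outer$y)
        body[row, col] <- min(d_in, d_out) > erosion_um
      }
    }
  }
  list(body = body, ribbon = ribbon)
}

# random smooth star-shaped boundary pair (simple and nested by construction)
random_boundary_pair <- function(field_um, n_vertices = 64) {
  th <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  r0 <- field_um * runif(1, 0.28, 0.36)
  wobble <- rep(0, n_vertices)
  for (k in 2:4)
    wobble <- wobble + runif(1, -0.08, 0.08) * cos(k * th + runif(1, 0, 2 * pi))
  r_out <- r0 * (1 + wobble)
  r_in <- r_out * runif(1, 0.3, 0.45)
  ctr <- field_um / 2 + runif(2, -0.03, 0.03) * field_um
  list(
    outer = boundary_polyline(ctr[1] + r_out * cos(th), ctr[2] + r_out * sin(th)),
    inner = boundary_polyline(ctr[1] + r_in * cos(th), ctr[2] + r_in * sin(th))
  )
}

# grayscale erosion/dilation by explicit offset sweep (replicate padding)
oracle_tophat <- function(mat, radius_px) {
  r <- radius_px
  off <- which(outer((-r):r, (-r):r, function(i, j) i * i + j * j) <= r^2,
               arr.ind = TRUE) - r - 1L
  pad_idx <- function(n) c(rep(1L, r), seq_len(n), rep(n, r))
  padded <- mat[pad_idx(nrow(mat)), pad_idx(ncol(mat))]
  sweep_filter <- function(m, fun, init) {
    acc <- matrix(init, nrow(mat), ncol(mat))
    for (k in seq_len(nrow(off))) {
      rows <- r + seq_len(nrow(mat)) + off[k, 1]
      cols <- r + seq_len(ncol(mat)) + off[k, 2]
      acc <- fun(acc, m[rows, cols])
    }
    acc
  }
  ero <- sweep_filter(padded, pmin, Inf)
  ero_p <- ero[pad_idx(nrow(mat)), pad_idx(ncol(mat))]
  open <- sweep_filter(ero_p, pmax, -Inf)
  pmax(mat - open, 0)
}

# studentized-range CDF by direct double numerical integration
oracle_ptukey_upper <- function(q, k, df) {
  inner_cdf <- function(s) {
    f <- function(z) stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - q * s))^(k - 1)
    k * stats::integrate(f, -8, 8, rel.tol = 1e-10)$value
  }
  dens_s <- function(s)
    2 * (df / 2)^(df / 2) / gamma(df / 2) * s^(df - 1) * exp(-df * s^2 / 2)
  g <- function(s) vapply(s, function(si) dens_s(si) * inner_cdf(si), 0)
  1 - stats::integrate(g, 0, Inf, rel.tol = 1e-9)$value
}

# minimal STORE-mode zip writer (for ImageJ RoiSet fixtures; no zip binary in
# the test environment)
crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    crc <- i
    for (j in 1:8)
      crc <- if (bitwAnd(crc, 1L)) bitwXor(bitwShiftR(crc, 1), -306674912L)
             else bitwShiftR(crc, 1)
    tab[i + 1] <- crc
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  for (b in as.integer(bytes))
    crc <- bitwXor(bitwShiftR(crc, 8),
                   crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1])
  bitwXor(crc, -1L)
}

write_store_zip <- function(files, zip_path) {
  con <- file(zip_path, "wb")
  on.exit(close(con))
  u32 <- function(x) writeBin(as.integer(x), con, 4, endian = "little")
  u16 <- function(x) writeBin(as.integer(x), con, 2, endian = "little")
  central <- list()
  offset <- 0
  for (nm in names(files)) {
    data <- files[[nm]]
    crc <- crc32(data)
    name_raw <- charToRaw(nm)
    u32(0x04034b50); u16(20); u16(0); u16(0); u16(0); u16(0)
    u32(crc); u32(length(data)); u32(length(data))
    u16(length(name_raw)); u16(0)
    writeBin(name_raw, con); writeBin(data, con)
    central[[nm]] <- list(crc = crc, size = length(data), offset = offset)
    offset <- offset + 30 + length(name_raw) + length(data)
  }
  cd_start <- offset
  for (nm in names(files)) {
    e <- central[[nm]]
    name_raw <- charToRaw(nm)
    u32(0x02014b50); u16(20); u16(20); u16(0); u16(0); u16(0); u16(0)
    u32(e$crc); u32(e$size); u32(e$size)
    u16(length(name_raw)); u16(0); u16(0); u16(0); u16(0); u32(0)
    u32(e$offset)
    writeBin(name_raw, con)
    offset <- offset + 46 + length(name_raw)
  }
  u32(0x06054b50); u16(0); u16(0)
  u16(length(files)); u16(length(files))
  u32(offset - cd_start); u32(cd_start); u16(0)
  invisible(zip_path)
}
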