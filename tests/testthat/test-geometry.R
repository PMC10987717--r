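# Body/Ribbon geometry in physical units

test_that("rasterization follows the pixel-centre even-odd rule", {
  # axis-aligned 10x10 um square aligned to pixel centres: exactly 100 pixels
  sq <- boundary_polyline(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_equal(sum(rasterize_polygon(sq, pixel_grid(12, 12, 1))), 100)

  # circle radius 10 um as a 256-gon at 0.1 um/px: area within 1% of pi*100
  th <- 2 * pi * (0:255) / 256
  circ <- boundary_polyline(12 + 10 * cos(th), 12 + 10 * sin(th))
  grid <- pixel_grid(240, 240, 0.1)
  area <- sum(rasterize_polygon(circ, grid)) * 0.1^2
  expect_lt(abs(area - pi * 100) / (pi * 100), 0.01)

  # and matches the scalar per-pixel oracle on a small grid
  g2 <- pixel_grid(40, 40, 0.6)
  mine <- rasterize_polygon(circ, g2)
  ref <- matrix(FALSE, 40, 40)
  for (col in 1:40) for (row in 1:40)
    ref[row, col] <- oracle_point_in_poly((col - 0.5) * 0.6, (row - 0.5) * 0.6,
                                          circ$x, circ$y)
  expect_identical(mine, ref)
})

test_that("degenerate polylines are rejected", {
  expect_error(boundary_polyline(1, 1), class = "oq_error_geometry")
  two <- boundary_polyline(c(0, 5), c(0, 5))
  expect_error(rasterize_polygon(two, pixel_grid(10, 10, 1)),
               class = "oq_error_geometry")
  bow <- boundary_polyline(c(0, 10, 10, 0), c(0, 10, 0, 10))  # self-crossing
  expect_error(rasterize_polygon(bow, pixel_grid(10, 10, 1)),
               class = "oq_error_geometry")
})

circle_poly <- function(r, ctr, n = 256) {
  th <- 2 * pi * (0:(n - 1)) / n
  boundary_polyline(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
}

test_that("body and ribbon masks hit their analytic areas", {
  px <- 0.2
  ctr <- c(33, 33)
  grid <- pixel_grid(330, 330, px)
  ch <- image_channel(matrix(0, 330, 330), grid)
  body <- build_body_mask(circle_poly(30, ctr), circle_poly(10, ctr), ch)
  body_area <- sum(body) * px^2
  expect_lt(abs(body_area - pi * (28.2^2 - 11.8^2)) / (pi * (28.2^2 - 11.8^2)),
            0.01)

  ribbon <- build_ribbon_mask(circle_poly(20, ctr), ch)
  ribbon_area <- sum(ribbon) * px^2
  expect_lt(abs(ribbon_area - 452.39) / 452.39, 0.01)
})

test_that("zero erosion returns the annulus; zero dilation only the line", {
  ctr <- c(16, 16)
  grid <- pixel_grid(160, 160, 0.2)
  ch <- image_channel(matrix(0, 160, 160), grid)
  outer <- circle_poly(12, ctr)
  inner <- circle_poly(5, ctr)
  annulus <- rasterize_polygon(outer, grid) & !rasterize_polygon(inner, grid)
  body0 <- build_body_mask(outer, inner, ch, erosion_um = 0)
  expect_identical(unclass(body0)[, ], annulus)

  # dilation 0: only pixels whose centres sit exactly on the boundary curve
  # (use dyadic coordinates so "exactly" is exact in floating point)
  grid4 <- pixel_grid(160, 160, 0.25)
  ch4 <- image_channel(matrix(0, 160, 160), grid4)
  seg <- boundary_polyline(c(0.125, 31.875), c(10.125, 10.125), closed = FALSE)
  rib0 <- build_ribbon_mask(seg, ch4, dilation_um = 0)
  expect_identical(unique(which(rib0, arr.ind = TRUE)[, "row"]), 41L)
  expect_equal(sum(rib0), 128)
})

test_that("body and ribbon are disjoint at the shared 1.8 um front", {
  ctr <- c(16, 16)
  grid <- pixel_grid(200, 200, 0.16)
  ch <- image_channel(matrix(0, 200, 200), grid)
  body <- build_body_mask(circle_poly(13, ctr), circle_poly(6, ctr), ch)
  ribbon <- build_ribbon_mask(circle_poly(6, ctr), ch)
  expect_false(any(body & ribbon))
  expect_gt(sum(body), 0)
  expect_gt(sum(ribbon), 0)
})

test_that("masks are monotone in erosion and dilation", {
  ctr <- c(15, 15)
  grid <- pixel_grid(120, 120, 0.25)
  ch <- image_channel(matrix(0, 120, 120), grid)
  outer <- circle_poly(12, ctr)
  inner <- circle_poly(4, ctr)
  prev_body <- NULL
  prev_rib <- NULL
  for (d in c(0, 0.9, 1.8, 3.2)) {
    body <- build_body_mask(outer, inner, ch, erosion_um = d)
    rib <- build_ribbon_mask(inner, ch, dilation_um = d)
    if (!is.null(prev_body)) {
      expect_true(all(which(body) %in% which(prev_body)))  # body shrinks
      expect_true(all(which(prev_rib) %in% which(rib)))    # ribbon grows
    }
    prev_body <- body
    prev_rib <- rib
  }
})

test_that("Otsu refinement removes exactly the dim sub-region", {
  ctr <- c(16, 16)
  grid <- pixel_grid(160, 160, 0.2)
  img <- matrix(200, 160, 160)
  img[, 1:80] <- 20  # left half dim
  ch <- image_channel(img, grid)
  body <- build_body_mask(circle_poly(13, ctr), circle_poly(5, ctr), ch,
                          refine = TRUE)
  plain <- build_body_mask(circle_poly(13, ctr), circle_poly(5, ctr), ch)
  thr <- attr(body, "otsu_threshold")
  expect_gt(thr, 20)
  expect_lte(thr, 200)
  expect_identical(unclass(body)[, ], unclass(plain)[, ] & (img >= thr))
})

test_that("inner boundary must lie inside the outer one", {
  grid <- pixel_grid(100, 100, 0.5)
  ch <- image_channel(matrix(0, 100, 100), grid)
  expect_error(
    build_body_mask(circle_poly(10, c(25, 25)), circle_poly(8, c(40, 40)), ch),
    class = "oq_error_geometry")
})

test_that("morphometrics recover symmetry and second-moment axes", {
  # circular rosette: aspect ratio 1 within 2%
  ctr <- c(16, 16)
  grid <- pixel_grid(160, 160, 0.2)
  ch <- image_channel(matrix(0, 160, 160), grid)
  roi <- rosette_roi(circle_poly(13, ctr), circle_poly(5, ctr), ch)
  m <- rosette_morphometrics(roi)
  expect_equal(m$aspect_ratio, 1, tolerance = 0.02)

  # area = body + ribbon band, lumen interior excluded
  px <- 0.1
  grid2 <- pixel_grid(660, 660, px)
  ch2 <- image_channel(matrix(0, 660, 660), grid2)
  roi2 <- rosette_roi(circle_poly(30, c(33, 33)), circle_poly(10, c(33, 33)), ch2)
  m2 <- rosette_morphometrics(roi2)
  analytic <- pi * (28.2^2 - 11.8^2) + pi * (11.8^2 - 8.2^2)
  expect_lt(abs(m2$area_um2 - analytic) / analytic, 0.01)

  # filled 40/20 um ellipse: aspect ratio 2, and the direct covariance oracle
  # agrees with the implementation's moment route
  th <- 2 * pi * (0:255) / 256
  outer <- boundary_polyline(45 + 40 * cos(th), 45 + 20 * sin(th))
  inner <- boundary_polyline(45 + 4 * cos(th), 45 + 2 * sin(th))
  grid3 <- pixel_grid(450, 450, 0.2)
  ch3 <- image_channel(matrix(0, 450, 450), grid3)
  roi3 <- rosette_roi(outer, inner, ch3, erosion_um = 0, dilation_um = 0.5)
  m3 <- rosette_morphometrics(roi3)
  expect_equal(m3$aspect_ratio, 2, tolerance = 0.02)
  filled <- rasterize_polygon(outer, grid3)
  idx <- which(filled, arr.ind = TRUE)
  cv <- stats::cov(cbind(idx[, 2], idx[, 1]))
  ev <- sort(eigen(cv, only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(m3$aspect_ratio, sqrt(ev[1] / ev[2]), tolerance = 0.005)
})

test_that("empty ROI is a degenerate error", {
  grid <- pixel_grid(60, 60, 0.5)
  ch <- image_channel(matrix(0, 60, 60), grid)
  roi <- rosette_roi(circle_poly(10, c(15, 15)), circle_poly(4, c(15, 15)), ch)
  roi$body[] <- FALSE
  roi$ribbon[] <- FALSE
  expect_error(rosette_morphometrics(roi), class = "oq_error_degenerate")
})

test_that("masks match the brute-force per-pixel oracle on random boundaries", {
  withr::with_seed(42, {
    for (rep in 1:3) {
      pair <- random_boundary_pair(field_um = 32, n_vertices = 48)
      grid <- pixel_grid(96, 96, 32 / 96)
      ch <- image_channel(matrix(0, 96, 96), grid)
      body <- build_body_mask(pair$outer, pair$inner, ch)
      ribbon <- build_ribbon_mask(pair$inner, ch)
      ref <- oracle_masks(pair$outer, pair$inner, grid, 1.8, 1.8)
      expect_identical(unclass(body)[, ], ref$body)
      expect_identical(unclass(ribbon)[, ], ref$ribbon)
    }
  })
})
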