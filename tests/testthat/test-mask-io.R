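test_that("readMask binarizes by the nonzero rule and round-trips PNG", {
  g <- matrix(0L, 3, 3); g[2, 2] <- 1L
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(g * 1.0, f)
  m <- readMask(f, "head")
  expect_identical(maskGrid(m), g)
  # low but nonzero intensity is still foreground (labels, not intensities)
  png::writePNG(g * (1 / 255), f)
  expect_identical(maskGrid(readMask(f, "head")), g)
  # all-zero raster is a valid (empty) mask
  png::writePNG(matrix(0, 4, 5), f)
  expect_identical(sum(maskGrid(readMask(f, "head"))), 0L)
  # binary write/read round trip is exact
  g2 <- matrix(rbinom(12 * 9, 1, 0.4), 12, 9)
  f2 <- withr::local_tempfile(fileext = ".png")
  writeMask(mkMask(g2), f2)
  expect_identical(maskGrid(readMask(f2, "stem")), matrix(as.integer(g2), 12, 9))
  # disagreeing color channels are rejected
  arr <- array(0, c(3, 3, 3)); arr[1, 1, 1] <- 1
  png::writePNG(arr, f2)
  expect_error(readMask(f2, "head"), "MULTI_CHANNEL")
})

test_that("YOLO polygon lines parse, denormalize and reject malformed input", {
  f <- withr::local_tempfile()
  writeLines("0 0 0 1 0 1 1 0 1", f)
  pg <- readYoloPolygons(f, 640, 640)
  expect_length(pg, 1L)
  expect_equal(pg[[1]]$classId, 0L)
  expect_equal(unname(coordPoints(pg[[1]]$contour)),
               cbind(c(0, 640, 640, 0), c(0, 0, 640, 640)))
  expect_true(pg[[1]]$contour@closed)
  writeLines("0 0.1 0.1 0.9 0.1 0.5", f)     # odd coordinate count
  expect_error(readYoloPolygons(f, 64, 64), "odd coordinate")
  writeLines("0 0.1 0.1 1.9 0.1 0.5 0.9", f) # out of [0,1]
  expect_error(readYoloPolygons(f, 64, 64), "outside")
  writeLines("0 0.1 0.1 0.9 0.2", f)         # < 3 vertices
  expect_error(readYoloPolygons(f, 64, 64), "fewer than 3")
})

test_that("rasterize-retrace round trip reproduces polygon vertices within 1 px", {
  f <- withr::local_tempfile()
  writeLines(c("0 0.1 0.1 0.9 0.1 0.9 0.9 0.1 0.9",
               "1 0.5 0.05 0.95 0.5 0.5 0.95 0.05 0.5"), f)
  polys <- readYoloPolygons(f, 640, 640)
  for (pg in polys) {
    m <- rasterizeContour(pg$contour, 640, 640, "head")
    tr <- coordPoints(extractOuterContour(m))
    v <- coordPoints(pg$contour)
    dmin <- vapply(seq_len(nrow(v)), function(i)
      min(sqrt((tr[, 1] - v[i, 1])^2 + (tr[, 2] - v[i, 2])^2)), numeric(1))
    expect_lt(max(dmin), 1 + 1e-9)
  }
})

test_that("largestComponent keeps the dominant blob and is idempotent", {
  g <- matrix(0L, 30, 30)
  g[5:14, 5:14] <- 1L                       # 100 px blob
  g[25, 25:27] <- 1L                        # 3 px blob
  m <- largestComponent(mkMask(g))
  expect_equal(sum(maskGrid(m)), 100L)
  expect_identical(maskGrid(largestComponent(m)), maskGrid(m))
  # single component: identity
  g2 <- matrix(0L, 10, 10); g2[2:5, 3:6] <- 1L
  expect_identical(maskGrid(largestComponent(mkMask(g2))), g2)
  expect_error(largestComponent(mkMask(matrix(0L, 5, 5))), "EMPTY")
})

test_that("largestComponent agrees with a brute-force flood fill on speckle", {
  set.seed(11)
  for (i in 1:5) {
    g <- matrix(rbinom(40 * 40, 1, 0.35), 40, 40)
    lab <- floodLabel(g)
    sizes <- tabulate(lab[lab > 0])
    expect_equal(sum(maskGrid(largestComponent(mkMask(g)))), max(sizes))
  }
})

test_that("outer contour has the expected pixel count and stays on the boundary", {
  # single pixel: degenerate one-point contour
  g1 <- matrix(0L, 5, 5); g1[3, 3] <- 1L
  ct1 <- extractOuterContour(mkMask(g1))
  expect_equal(unname(coordPoints(ct1)), cbind(2, 2))
  # filled 10x10 square: 36 boundary pixels, bounding box preserved
  g2 <- matrix(0L, 20, 20); g2[6:15, 6:15] <- 1L
  ct2 <- coordPoints(extractOuterContour(mkMask(g2)))
  expect_equal(nrow(ct2), 36L)
  expect_equal(range(ct2[, 1]), c(5, 14))
  expect_equal(range(ct2[, 2]), c(5, 14))
  # starts topmost-then-leftmost and consecutive points are 8-neighbors
  expect_equal(unname(ct2[1, ]), c(5, 5))
  steps <- abs(diff(ct2))
  expect_true(all(steps <= 1))
  # rasterized ellipse: every contour point within 1 px of the true curve
  e <- mkEllipse(60, 50, 80, 50, 25)
  xs <- matrix(0:119, 100, 120, byrow = TRUE); ys <- matrix(0:99, 100, 120)
  g3 <- matrix(as.integer(ellipseImplicit(e, xs, ys) <= 0), 100, 120)
  ct3 <- coordPoints(extractOuterContour(mkMask(g3)))
  bnd <- ellipseBoundaryPoints(e, 3000)
  dmin <- vapply(seq_len(nrow(ct3)), function(i)
    min(sqrt((bnd[, 1] - ct3[i, 1])^2 + (bnd[, 2] - ct3[i, 2])^2)),
    numeric(1))
  expect_lt(max(dmin), 1)
  # contour points lie inside the mask bounds and on foreground
  expect_true(all(g3[cbind(ct3[, 2] + 1, ct3[, 1] + 1)] == 1L))
})

test_that("centerline midpoints follow bars, even widths and slanted bands", {
  # vertical bar columns 4-6 (0-based), rows 0-19
  g <- matrix(0L, 20, 20); g[1:20, 5:7] <- 1L
  cl <- extractCenterline(mkMask(g, "stem"))
  expect_equal(scanAxis(cl), "y-major")
  expect_equal(nrow(coordPoints(cl)), 20L)
  expect_true(all(coordPoints(cl)[, 1] == 5))
  # even width (columns 4-7): midpoint convention gives 5.5
  g2 <- matrix(0L, 20, 20); g2[1:20, 5:8] <- 1L
  expect_true(all(coordPoints(extractCenterline(mkMask(g2, "stem")))[, 1] == 5.5))
  # slanted band around x = 40 + 0.35 y: centerline within 0.75 px
  H <- 128; W <- 128
  g3 <- matrix(0L, H, W)
  for (r in 1:H) {
    cx <- 40 + 0.35 * (r - 1)
    g3[r, max(1, ceiling(cx - 5 + 1)):min(W, floor(cx + 5 + 1))] <- 1L
  }
  cl3 <- extractCenterline(mkMask(g3, "stem"))
  p <- coordPoints(cl3)
  dev <- p[, 1] - (40 + 0.35 * p[, 2])
  expect_lt(max(abs(dev)), 0.75)
  # guards
  expect_error(extractCenterline(mkMask(matrix(0L, 5, 5), "stem")),
               "EMPTY_STEM")
  g4 <- matrix(0L, 10, 10); g4[2:4, 5] <- 1L
  expect_error(extractCenterline(mkMask(g4, "stem")), "CENTERLINE_TOO_SHORT")
})

test_that("centerline keeps the longest run when a scanline is split", {
  g <- matrix(0L, 40, 30)
  g[1:40, 5:8] <- 1L      # main band (width 4) at x = 4..7
  g[1:40, 20:21] <- 1L    # narrower parallel speckle band
  cl <- extractCenterline(mkMask(g, "stem"))
  expect_true(all(coordPoints(cl)[, 1] == 5.5))
})
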