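test_that("stem-ellipse intersection handles crossings, selection and fallback", {
  # circle r = 5 at origin, vertical stem x = 0 entering from below
  circ <- mkEllipse(0, 0, 10, 10, 0)
  stp <- mkStemPoly(c(0), 2, "y-major", c(5, 30))
  ip <- intersectStemEllipse(stp, circ, c(0, 5))
  expect_equal(ip@selection, "exact_root")
  expect_equal(c(ip@x, ip@y), c(0, 5), tolerance = 1e-9)
  expect_equal(ip@nRealRoots, 2L)
  # ellipse x^2/25 + y^2/9 = 1 with y = 0.1 x: x = +-sqrt(1/(1/25 + 0.01/9));
  # head end at (5, 0.5) selects the positive root
  ell <- mkEllipse(0, 0, 10, 6, 0)
  stx <- mkStemPoly(c(0, 0.1), 3, "x-major", c(0, 10))
  ipx <- intersectStemEllipse(stx, ell, c(5, 0.5))
  xExpect <- sqrt(1 / (1 / 25 + 0.01 / 9))
  expect_equal(ipx@x, xExpect, tolerance = 1e-9)
  expect_equal(ipx@y, 0.1 * xExpect, tolerance = 1e-9)
  expect_equal(ipx@selection, "exact_root")
  # the exact root satisfies the implicit system in normalized coordinates
  expect_lt(abs(ellipseImplicit(ell, ipx@x, ipx@y)), 1e-6)
  # disjoint geometry: fallback flagged
  far <- mkStemPoly(c(100), 2, "y-major", c(120, 200))
  ipf <- intersectStemEllipse(far, ell, c(100, 120))
  expect_equal(ipf@selection, "closest_approach_fallback")
})

test_that("intersection matches the dense-sampling sign-change oracle", {
  ps <- sampleSceneParams(30, c(70, 120), seed = 314)
  for (p in ps) {
    poly <- mkStemPoly(p@stemCoeffs[1:4], 3, p@stemFrame, p@stemDomain)
    ctr <- ellipseCenter(p@ellipse)
    ends <- DiskTilt:::stemPoint(poly, p@stemDomain)
    d2 <- (ends[, 1] - ctr[1])^2 + (ends[, 2] - ctr[2])^2
    headEnd <- ends[which.min(d2), ]
    ip <- intersectStemEllipse(poly, p@ellipse, headEnd)
    tOracle <- denseIntersectOracle(poly, p@ellipse, headEnd, 2e4)
    expect_false(is.null(tOracle))
    pO <- DiskTilt:::stemPoint(poly, tOracle)
    expect_lt(sqrt((ip@x - pO[1])^2 + (ip@y - pO[2])^2), 0.5)
  }
})

test_that("the acute angle formula handles parallel, perpendicular and vertical lines", {
  expect_equal(tiltAngleAcute(0.7, 0.7), 0)
  expect_equal(tiltAngleAcute(1, -1), 90)           # 1 + kl ks = 0
  expect_equal(tiltAngleAcute(2, 0.5), 36.8699, tolerance = 1e-4)
  expect_equal(tiltAngleAcute(2, 0.5), atan(1.5 / 2) * 180 / pi)
  expect_equal(tiltAngleAcute(Inf, Inf), 0)         # both vertical: parallel
  expect_equal(tiltAngleAcute(Inf, 1), 45)
  expect_equal(tiltAngleAcute(0, Inf), 90)
  # symmetry, and zero iff equal
  set.seed(81)
  for (i in 1:50) {
    kl <- rt(1, 3); ks <- rt(1, 3)
    expect_equal(tiltAngleAcute(kl, ks), tiltAngleAcute(ks, kl))
    if (kl != ks) expect_gt(tiltAngleAcute(kl, ks), 0)
  }
})

test_that("the oriented angle spans [0, 180) and is consistent with the acute form", {
  expect_equal(tiltAngleOriented(c(1, 0), c(0, 1)), 90)
  expect_equal(tiltAngleOriented(c(1, 0), c(-0.5, sqrt(3) / 2)), 120)
  expect_error(tiltAngleOriented(c(0, 0), c(1, 0)), "ZERO_VECTOR")
  # min(theta, 180 - theta) equals the acute slope formula
  set.seed(91)
  for (i in 1:200) {
    aAng <- runif(1, -pi / 2 + 1e-3, pi / 2 - 1e-3)
    tAng <- runif(1, 0, 2 * pi)
    axis <- c(cos(aAng), sin(aAng))
    tang <- c(cos(tAng), sin(tAng))
    th <- tiltAngleOriented(axis, tang)
    kl <- tan(aAng)
    ks <- if (abs(cos(tAng)) < 1e-12) Inf else tan(tAng)
    expect_equal(min(th, 180 - th), tiltAngleAcute(kl, ks),
                 tolerance = 1e-9)
  }
})

test_that("analytic scenes keep their angle under rotation and scaling", {
  set.seed(101)
  for (i in 1:20) {
    aAng <- runif(1, -50, 50) * pi / 180    # axis safely off vertical
    tAng <- runif(1, 0, 2 * pi)
    axis <- c(cos(aAng), sin(aAng))
    tang <- c(cos(tAng), sin(tAng))
    base <- tiltAngleOriented(axis, tang)
    phi <- runif(1, -30, 30) * pi / 180     # rotation keeping axis right-half
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    expect_equal(tiltAngleOriented(R %*% axis, R %*% tang), base,
                 tolerance = 1e-9)
    # acute convention is invariant under any rotation
    phi2 <- runif(1, 0, 2 * pi)
    R2 <- matrix(c(cos(phi2), sin(phi2), -sin(phi2), cos(phi2)), 2, 2)
    slopeOf <- function(v) if (abs(v[1]) < 1e-12) Inf else v[2] / v[1]
    expect_equal(tiltAngleAcute(slopeOf(R2 %*% axis), slopeOf(R2 %*% tang)),
                 min(base, 180 - base), tolerance = 1e-9)
    # uniform scaling leaves directions, hence the angle, untouched
    s <- runif(1, 0.1, 10)
    expect_equal(tiltAngleOriented(s * axis, s * tang), base,
                 tolerance = 1e-12)
  }
})

test_that("measureTilt recovers ground truth and reports both conventions", {
  p75 <- sampleSceneParams(1, c(75, 75), seed = 7)[[1]]
  sc <- generateScene(p75)
  m <- measureTilt(sc$head, sc$stem)
  expect_equal(angleMode(m), "oriented")
  expect_lt(abs(angleDeg(m) - 75), 1)
  # an obtuse configuration: oriented ~106, acute ~74 (supplementary)
  p106 <- sampleSceneParams(1, c(106, 106), seed = 8)[[1]]
  sc2 <- generateScene(p106)
  mo <- measureTilt(sc2$head, sc2$stem)
  ma <- measureTilt(sc2$head, sc2$stem, tiltConfig(mode = "acute"))
  expect_lt(abs(angleDeg(mo) - 106), 1)
  expect_lt(abs(angleDeg(ma) - 74), 1)
  expect_equal(angleDeg(mo) + angleDeg(ma), 180, tolerance = 1e-9)
  # guards carry distinct diagnostic codes
  empty <- mkMask(matrix(0L, 8, 8), "stem")
  expect_error(measureTilt(sc$head, empty), "EMPTY_STEM")
  expect_error(measureTilt(mkMask(matrix(0L, 8, 8)), sc$stem), "EMPTY_HEAD")
})

test_that("measured angles survive 90-degree mask rotation in the acute convention", {
  p <- sampleSceneParams(1, c(80, 80), seed = 12)[[1]]
  sc <- generateScene(p)
  rot90 <- function(m, lab) mkMask(t(maskGrid(m))[rev(seq_len(ncol(maskGrid(m)))), ], lab)
  base <- angleDeg(measureTilt(sc$head, sc$stem, tiltConfig(mode = "acute")))
  mR <- measureTilt(rot90(sc$head, "head"), rot90(sc$stem, "stem"),
                    tiltConfig(mode = "acute"))
  expect_lt(abs(angleDeg(mR) - base), 0.5)
})

test_that("instance pairing matches heads to their stems", {
  mkScenePair <- function(seedA, seedB) {
    pA <- sampleSceneParams(1, c(85, 85), seed = seedA,
                            imageSize = c(256L, 256L))[[1]]
    pB <- sampleSceneParams(1, c(95, 95), seed = seedB,
                            imageSize = c(256L, 256L))[[1]]
    list(generateScene(pA), generateScene(pB))
  }
  scs <- mkScenePair(3, 4)
  # place plant B in the right half of a wide canvas
  widen <- function(m, offset, lab) {
    g <- matrix(0L, 256, 640)
    g[, offset + seq_len(256)] <- maskGrid(m)
    mkMask(g, lab)
  }
  heads <- list(widen(scs[[1]]$head, 0, "head"),
                widen(scs[[2]]$head, 384, "head"))
  stems <- list(widen(scs[[1]]$stem, 0, "stem"),
                widen(scs[[2]]$stem, 384, "stem"))
  pr <- pairInstances(heads, stems)
  expect_equal(pr$pairs$stem[order(pr$pairs$head)], c(1L, 2L))
  expect_length(pr$unpairedHeads, 0)
  # brute-force assignment oracle: both possible assignments compared
  centroid <- function(m) {
    idx <- which(maskGrid(m) == 1L, arr.ind = TRUE)
    c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
  }
  stemEnd <- function(s, hc) {
    cl <- extractCenterline(largestComponent(s))
    e <- coordPoints(cl)[c(1, nrow(coordPoints(cl))), ]
    min(sqrt((e[, 1] - hc[1])^2 + (e[, 2] - hc[2])^2))
  }
  cost <- function(assign) sum(vapply(1:2, function(i)
    stemEnd(stems[[assign[i]]], centroid(heads[[i]])), numeric(1)))
  best <- if (cost(c(1, 2)) <= cost(c(2, 1))) c(1L, 2L) else c(2L, 1L)
  expect_equal(pr$pairs$stem[order(pr$pairs$head)], best)
  # surplus heads are reported unpaired
  pr2 <- pairInstances(heads, stems[1])
  expect_equal(nrow(pr2$pairs), 1L)
  expect_length(pr2$unpairedHeads, 1L)
  expect_error(pairInstances(list(), stems), "EMPTY_LIST")
  # 1 head, 1 stem: the single pair
  pr1 <- pairInstances(heads[1], stems[1])
  expect_equal(pr1$pairs$head, 1L)
  expect_equal(pr1$pairs$stem, 1L)
})

test_that("measurement configuration round-trips through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("order: 4", "mode: acute", "rootExtend: 0.3"), f)
  cfg <- readTiltConfig(f)
  expect_equal(cfg$order, 4L)
  expect_equal(cfg$mode, "acute")
  expect_equal(cfg$rootExtend, 0.3)
  expect_equal(cfg$tangentExtend, 0.1)    # untouched default
  writeLines("bogusKey: 1", f)
  expect_error(readTiltConfig(f), "BAD_CONFIG")
})
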