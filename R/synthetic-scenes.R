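# Ground-truth scene generation: an elliptical head attached to a smoothly
# curved stem band, with the analytic tilt angle known exactly, plus the
# augmentation and dataset-split bookkeeping utilities used around the
# segmentation training data.
#
# Every operation is a pure function of (params, seed): identical inputs
# give bit-identical masks.

# Analytic oriented tilt angle of a parameter set: intersect the generating
# stem polynomial with the generating ellipse and take the angle at the
# crossing. Recomputable from the geometry alone (no rasterization).

#' Analytic oriented tilt angle of a scene's generating geometry
#'
#' @param params a [SceneParams-class].
#' @return oriented angle in degrees.
#' @export
analyticSceneAngle <- function(params) {
  ord <- max(2L, min(4L, max(which(params@stemCoeffs != 0), 2L) - 1L))
  co <- params@stemCoeffs
  if (ord < 4L) co[(ord + 2L):5L] <- 0
  poly <- new("StemPolynomial", coeffs = co, order = ord,
              frame = params@stemFrame, domain = params@stemDomain, rss = 0)
  ctr <- ellipseCenter(params@ellipse)
  endT <- params@stemDomain
  pts <- stemPoint(poly, endT)
  d2 <- (pts[, 1L] - ctr[[1L]])^2 + (pts[, 2L] - ctr[[2L]])^2
  headEnd <- pts[which.min(d2), ]
  ip <- intersectStemEllipse(poly, params@ellipse, headEnd)
  ax <- majorAxis(params@ellipse)
  tiltAngleOriented(ax@v, orientedTangentDir(poly, ip@t))
}

#' Sample synthetic scene parameter sets
#'
#' Draws \code{n} parameter sets whose analytic oriented angles are
#' exactly uniform over \code{angleRange}: the target angle is sampled
#' uniformly first, and the ellipse/stem geometry is then constructed to
#' realize it (the stem tangent at the attachment point is placed at the
#' sampled angle from the major axis). Geometry that would leave the
#' image bounds is rejected and redrawn without touching the sampled
#' angle, so the angle distribution is unaffected.
#'
#' @param n number of scenes (>= 1).
#' @param angleRange degrees, default c(70, 120) — the span observed for
#'   field-grown heads.
#' @param seed integer seed; the whole draw is deterministic in it.
#' @param imageSize c(height, width) px, default 512 x 512.
#' @param jitterPx boundary perturbation scale stored in each parameter
#'   set (default 0).
#' @return list of [SceneParams-class].
#' @export
sampleSceneParams <- function(n, angleRange = c(70, 120), seed = 1L,
                              imageSize = c(512L, 512L), jitterPx = 0) {
  stopifnot(n >= 1L, length(angleRange) == 2L,
            angleRange[1L] <= angleRange[2L])
  if (angleRange[1L] < 1 || angleRange[2L] > 179)
    diskTiltError("BAD_RANGE", "angleRange must lie within [1, 179] degrees")
  H <- as.integer(imageSize[[1L]]); W <- as.integer(imageSize[[2L]])
  withSeed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      alpha <- stats::runif(1L, angleRange[1L], angleRange[2L])
      for (try in seq_len(200L)) {
        thetaE <- stats::runif(1L, -55, 55)
        aFull <- stats::runif(1L, 130, 210) * (H / 512)
        bFull <- aFull * stats::runif(1L, 0.55, 0.85)
        h <- stats::runif(1L, 0.38, 0.62) * W
        k <- stats::runif(1L, 0.22, 0.40) * H
        thr <- degToRad(thetaE)
        u <- c(cos(thr), sin(thr))
        # tangent direction at the sampled oriented angle from the axis
        ar <- degToRad(alpha)
        d <- c(cos(-ar) * u[1L] - sin(-ar) * u[2L],
               sin(-ar) * u[1L] + cos(-ar) * u[2L])
        if (d[2L] > -0.35) next        # keep the stem y-major and upward
        slope0 <- d[1L] / d[2L]        # dx/dy at the attachment
        if (abs(slope0) > 2) next
        sa <- aFull / 2; sb <- bFull / 2
        # attachment: boundary point whose parametric direction matches the
        # downward continuation of the stem
        w <- c(cos(-thr) * (-d[1L]) - sin(-thr) * (-d[2L]),
               sin(-thr) * (-d[1L]) + cos(-thr) * (-d[2L]))
        phi <- atan2(w[2L] / sb, w[1L] / sa)
        P <- c(h + sa * cos(phi) * cos(thr) - sb * sin(phi) * sin(thr),
               k + sa * cos(phi) * sin(thr) + sb * sin(phi) * cos(thr))
        y0 <- P[2L]
        L <- stats::runif(1L, 0.35, 0.55) * H
        yEnd <- min(H - 3, y0 + L)
        if (yEnd - y0 < 0.23 * H) next
        c2 <- stats::runif(1L, -2e-4, 2e-4)
        c3 <- stats::runif(1L, -6e-7, 6e-7)
        # x = P_x + s0 (y - y0) + c2 (y - y0)^2 + c3 (y - y0)^3, expanded
        shift <- c(-y0, 1)
        coeffs <- c(P[1L])
        pw <- 1
        for (cj in c(slope0, c2, c3)) {
          pw <- polyMul(pw, shift)
          coeffs <- polyAdd(coeffs, cj * pw)
        }
        coeffs <- c(coeffs, rep(0, 5 - length(coeffs)))
        bandW <- stats::runif(1L, 10, 16)
        # bounds: ellipse bbox then the band over its whole domain
        ex <- sqrt((sa * cos(thr))^2 + (sb * sin(thr))^2)
        ey <- sqrt((sa * sin(thr))^2 + (sb * cos(thr))^2)
        if (h - ex < 4 || h + ex > W - 5 || k - ey < 4 || k + ey > H - 5) next
        yy <- seq(y0, yEnd, length.out = 64L)
        cx <- polyEval(coeffs, yy)
        hwMax <- bandW / 2 * sqrt(1 + polyEval(polyDeriv(coeffs), yy)^2)
        if (any(cx - hwMax < 2) || any(cx + hwMax > W - 3)) next
        ell <- new("EllipseParams", h = h, k = k, a = aFull, b = bFull,
                   thetaDeg = thetaE)
        return(new("SceneParams", imageSize = c(H, W), ellipse = ell,
                   stemCoeffs = coeffs, stemFrame = "y-major",
                   stemDomain = c(y0, yEnd), bandWidthPx = bandW,
                   trueAngleDeg = alpha,
                   trueAcuteDeg = min(alpha, 180 - alpha),
                   jitterPx = jitterPx, seed = seeds[[i]]))
      }
      diskTiltError("UNSATISFIABLE_RANGE",
                    "could not realize the requested angle in bounds")
    })
  })
}

# Seeded boundary jitter: each pixel within jitterPx-scaled reach of the
# mask boundary flips with probability 0.5 * exp(-d / jitterPx), d being
# the 8-neighbor (chessboard) distance to the foreground/background
# interface. A simple, seedable stand-in for segmentation-mask raggedness.
applyJitter <- function(grid, jitterPx) {
  maxd <- max(2L, as.integer(ceiling(6 * jitterPx)))
  d <- boundaryDistanceField(grid, maxd)
  prob <- 0.5 * exp(-d / jitterPx)
  flip <- is.finite(d) & stats::runif(length(grid)) < prob
  grid[flip] <- 1L - grid[flip]
  grid
}

#' Rasterize a synthetic scene
#'
#' Renders the filled head ellipse and a constant-width band around the
#' stem curve (per-scanline half-width scaled by the local slope so the
#' perpendicular width stays near-constant and scanline midpoints fall
#' exactly on the generating curve). Stem pixels strictly inside the head
#' ellipse are removed, as in per-class instance masks. With
#' \code{jitterPx > 0}, boundary-adjacent pixels flip under the seeded
#' generator.
#'
#' @param params a [SceneParams-class].
#' @return list with \code{head}, \code{stem} ([BinaryMask-class]) and
#'   \code{truth} (list: trueAngleDeg, trueAcuteDeg and the generating
#'   geometry).
#' @export
generateScene <- function(params) {
  H <- params@imageSize[[1L]]; W <- params@imageSize[[2L]]
  ell <- params@ellipse
  xs <- matrix(0:(W - 1L), H, W, byrow = TRUE)
  ys <- matrix(0:(H - 1L), H, W)
  headGrid <- matrix(as.integer(ellipseImplicit(ell, xs, ys) <= 0), H, W)
  if (!any(headGrid == 1L))
    diskTiltError("GEOMETRY_OUT_OF_BOUNDS", "head ellipse rasterized empty")
  stemGrid <- matrix(0L, H, W)
  dom <- params@stemDomain
  rows <- seq(max(0L, ceiling(dom[1L])), min(H - 1L, floor(dom[2L])))
  if (length(rows) < 4L)
    diskTiltError("GEOMETRY_OUT_OF_BOUNDS", "stem band outside image")
  cx <- polyEval(params@stemCoeffs, rows)
  hw <- params@bandWidthPx / 2 *
    sqrt(1 + polyEval(polyDeriv(params@stemCoeffs), rows)^2)
  for (i in seq_along(rows)) {
    lo <- max(0L, ceiling(cx[i] - hw[i])); hi <- min(W - 1L, floor(cx[i] + hw[i]))
    if (lo <= hi) stemGrid[rows[i] + 1L, (lo + 1L):(hi + 1L)] <- 1L
  }
  inside <- ellipseImplicit(ell, xs, ys) < 0
  stemGrid[inside] <- 0L
  if (!any(stemGrid == 1L))
    diskTiltError("GEOMETRY_OUT_OF_BOUNDS", "stem does not reach the image")
  if (params@jitterPx > 0) {
    withSeed(params@seed, {
      headGrid <- applyJitter(headGrid, params@jitterPx)
      stemGrid <- applyJitter(stemGrid, params@jitterPx)
    })
  }
  list(head = new("BinaryMask", grid = headGrid, classLabel = "head"),
       stem = new("BinaryMask", grid = stemGrid, classLabel = "stem"),
       truth = list(trueAngleDeg = params@trueAngleDeg,
                    trueAcuteDeg = params@trueAcuteDeg,
                    ellipse = asList(params@ellipse),
                    stemCoeffs = as.numeric(params@stemCoeffs),
                    stemDomain = as.numeric(params@stemDomain),
                    bandWidthPx = params@bandWidthPx,
                    jitterPx = params@jitterPx, seed = params@seed))
}

#' Augmentation configuration constructor
#'
#' Defaults are the ranges used to augment the segmentation training
#' images: brightness in -50\% to +50\%, rotation in -90 to +90 degrees,
#' Gaussian noise with standard deviation in 0--20\% of full scale.
#'
#' @param brightnessRange,rotationRange,noiseRange numeric length-2 ranges.
#' @param seed integer RNG seed.
#' @return an [AugmentationConfig-class].
#' @export
augmentationConfig <- function(brightnessRange = c(-0.5, 0.5),
                               rotationRange = c(-90, 90),
                               noiseRange = c(0, 0.2), seed = 1L) {
  new("AugmentationConfig", brightnessRange = brightnessRange,
      rotationRange = rotationRange, noiseRange = noiseRange,
      seed = as.integer(seed))
}

#' Apply brightness / rotation / noise augmentation to a grayscale image
#'
#' Draws one brightness factor, one rotation angle and one noise level
#' from the configured ranges (independently, under the configured seed),
#' then applies them in that order. Intensities are clamped to [0, 1].
#'
#' @param image numeric matrix in [0, 1].
#' @param config an [AugmentationConfig-class].
#' @return augmented numeric matrix, same size.
#' @export
augmentImage <- function(image, config = augmentationConfig()) {
  stopifnot(is.matrix(image))
  withSeed(config@seed, {
    b <- stats::runif(1L, config@brightnessRange[1L], config@brightnessRange[2L])
    out <- clamp(image * (1 + b), 0, 1)
    ang <- stats::runif(1L, config@rotationRange[1L], config@rotationRange[2L])
    if (ang != 0) out <- rotateBilinear(out, ang)
    nsd <- stats::runif(1L, config@noiseRange[1L], config@noiseRange[2L])
    if (nsd > 0)
      out <- clamp(out + matrix(stats::rnorm(length(out), 0, nsd),
                                nrow(out), ncol(out)), 0, 1)
    out
  })
}

#' Seeded train/validation/test split
#'
#' Random permutation under the seed, then contiguous assignment by
#' rounded ratio counts (the last part absorbs the rounding remainder so
#' the three parts partition the input). Shares are reported as
#' percentages of the full list rounded to 2 decimals.
#'
#' @param ids character or integer vector of item ids.
#' @param ratios numeric length-3 nonnegative (train, val, test) weights.
#' @param seed integer seed.
#' @return list with \code{assignment} (data.frame id, split),
#'   \code{counts} and \code{sharesPct}.
#' @export
splitDataset <- function(ids, ratios = c(8, 1, 1), seed = 1L) {
  if (!length(ids)) diskTiltError("EMPTY_IDS", "empty id list")
  if (length(ratios) != 3L || any(ratios < 0) || sum(ratios) <= 0)
    diskTiltError("BAD_RATIOS", "ratios must be 3 nonnegative values, sum > 0")
  n <- length(ids)
  counts <- round(ratios / sum(ratios) * n)
  counts[3L] <- n - counts[1L] - counts[2L]
  if (counts[3L] < 0) {        # rounding overshoot: take it from the largest
    counts[which.max(counts[1:2])] <- counts[which.max(counts[1:2])] + counts[3L]
    counts[3L] <- 0
  }
  perm <- withSeed(seed, sample(ids))
  split <- rep(c("train", "val", "test"), counts)
  names(counts) <- c("train", "val", "test")
  list(assignment = data.frame(id = perm, split = split,
                               stringsAsFactors = FALSE),
       counts = counts,
       sharesPct = splitShares(counts, n))
}

#' Dataset-accounting shares
#'
#' Each count as a percentage of the full collection, truncated to 2
#' decimals — the bookkeeping used when a split is reported against the
#' total number of acquired images rather than the usable subset.
#' (Truncation, not rounding: 220/1163 is reported as 18.91\%, which only
#' truncation produces.)
#'
#' @param counts named or unnamed numeric counts.
#' @param total the full collection size.
#' @return numeric percentages, truncated to 2 decimals.
#' @export
splitShares <- function(counts, total)
  floor(counts / total * 100 * 100 + 1e-9) / 100
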