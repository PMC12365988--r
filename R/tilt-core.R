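# Stem-ellipse intersection, tangent extraction and the tilt angle itself;
# orchestration of the full mask-to-angle measurement.
#
# Two angle conventions are provided. The acute convention
#   theta = arctan(|(kl - ks) / (1 + kl ks)|)
# maps every configuration into [0, 90]. The oriented convention takes the
# angle between the major axis oriented toward increasing x and the stem
# tangent oriented from the stem interior toward the intersection point,
# spanning [0, 180) and so distinguishing supplementary configurations
# (a head leaning "with" vs. "against" its stem). Field measurements of
# head inclination are commonly reported as obtuse values, which only the
# oriented convention can produce; min(theta, 180 - theta) always equals
# the acute value.

#' Measurement configuration
#'
#' Central place for the pipeline's numerical choices: the polynomial
#' order, the angle convention, the domain-extension margins (masks often
#' stop short of the ellipse boundary; bounded extrapolation bridges the
#' gap without runaway cubic behavior), and the root/on-curve tolerances.
#'
#' @param order stem polynomial order (default 3).
#' @param mode \code{"oriented"} (default) or \code{"acute"}.
#' @param rootExtend relative domain extension for root admissibility
#'   (default 0.25).
#' @param tangentExtend relative domain extension for tangent evaluation
#'   (default 0.10).
#' @param rootImagTol relative imaginary-part tolerance for real roots
#'   (default 1e-8).
#' @param onCurveTol on-curve verification tolerance in normalized ellipse
#'   coordinates (default 1e-6).
#' @param contourStride uniform subsampling stride for very dense contours
#'   (default 1 = every point).
#' @param headClearFactor centerline scanlines closer to the fitted head
#'   boundary than this multiple of the stem width are dropped before the
#'   stem fit (their runs are clipped by the head, which biases the
#'   midpoints); 0 disables the trim. Default 1.
#' @return a named list of settings.
#' @export
tiltConfig <- function(order = 3L, mode = c("oriented", "acute"),
                       rootExtend = 0.25, tangentExtend = 0.10,
                       rootImagTol = 1e-8, onCurveTol = 1e-6,
                       contourStride = 1L, headClearFactor = 1) {
  list(order = as.integer(order), mode = match.arg(mode),
       rootExtend = rootExtend, tangentExtend = tangentExtend,
       rootImagTol = rootImagTol, onCurveTol = onCurveTol,
       contourStride = as.integer(contourStride),
       headClearFactor = headClearFactor)
}

#' Read a measurement configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return the configuration list of [tiltConfig()].
#' @export
readTiltConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(tiltConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    diskTiltError("BAD_CONFIG", paste("unknown config keys:",
                                      paste(bad, collapse = ", ")))
  do.call(tiltConfig, vals)
}

# Real eigenvalue roots of an ascending-coefficient polynomial via the
# companion matrix.
companionRoots <- function(coeffs, imagTol = 1e-8) {
  scale <- max(abs(coeffs))
  coeffs <- coeffs / scale
  while (length(coeffs) > 1L &&
         abs(coeffs[[length(coeffs)]]) < 1e-13) coeffs <- coeffs[-length(coeffs)]
  deg <- length(coeffs) - 1L
  if (deg < 1L) return(complex(0))
  monic <- coeffs / coeffs[[length(coeffs)]]
  if (deg == 1L) return(as.complex(-monic[[1L]]))
  Cm <- matrix(0, deg, deg)
  Cm[cbind(2:deg, 1:(deg - 1L))] <- 1
  Cm[, deg] <- -monic[1:deg]
  eigen(Cm, only.values = TRUE)$values
}

#' Intersect the stem polynomial with the head ellipse
#'
#' Substituting the polynomial into the implicit ellipse equation yields a
#' univariate polynomial whose real roots (companion-matrix eigenvalues
#' with |Im| <= rootImagTol * (1 + |Re|)) are the crossings. Among real
#' roots within the polynomial domain extended by \code{rootExtend} on
#' each side, the one whose point lies nearest \code{headEnd} is returned.
#' When no admissible real root exists (disjoint masks), the curve point
#' of minimum distance to the ellipse boundary is returned with
#' \code{selection = "closest_approach_fallback"}.
#'
#' @param poly a [StemPolynomial-class].
#' @param ellipse an [EllipseParams-class].
#' @param headEnd numeric (x, y): the centerline endpoint nearest the
#'   ellipse center.
#' @param rootExtend,rootImagTol see [tiltConfig()].
#' @return an [IntersectionPoint-class].
#' @export
intersectStemEllipse <- function(poly, ellipse, headEnd,
                                 rootExtend = 0.25, rootImagTol = 1e-8) {
  th <- ellipseThetaRad(ellipse)
  sa <- ellipse@a / 2; sb <- ellipse@b / 2
  co <- cos(th); si <- sin(th)
  dom <- poly@domain
  # center/scale the parameter (t = tm + hw u, u in about [-1, 1]) so the
  # companion-matrix eigenproblem stays well conditioned in pixel coords
  tm <- mean(dom); hw <- max(diff(dom) / 2, 1)
  toU <- function(coeffs) {
    lin <- c(tm, hw)
    out <- c(coeffs[[1L]]); pw <- 1
    for (j in seq_along(coeffs)[-1L]) {
      pw <- polyMul(pw, lin)
      out <- polyAdd(out, coeffs[[j]] * pw)
    }
    out
  }
  f <- toU(poly@coeffs)
  if (poly@frame == "x-major") {          # x(u) = tm + hw u, y(u) = f(u)
    xt <- c(tm, hw); yt <- f
  } else {                                # x(u) = f(u), y(u) = tm + hw u
    xt <- f; yt <- c(tm, hw)
  }
  dx <- xt; dx[1L] <- dx[1L] - ellipse@h
  dy <- yt; dy[1L] <- dy[1L] - ellipse@k
  X <- polyAdd(co * dx, si * dy)
  Y <- polyAdd(-si * dx, co * dy)
  P <- polyAdd(polyMul(X, X) / sa^2, polyMul(Y, Y) / sb^2)
  P[1L] <- P[1L] - 1
  roots <- companionRoots(P, rootImagTol)
  isReal <- abs(Im(roots)) <= rootImagTol * (1 + abs(Re(roots)))
  realRoots <- tm + hw * Re(roots[isReal])
  ext <- rootExtend * diff(dom)
  admissible <- realRoots[realRoots >= dom[1L] - ext &
                            realRoots <= dom[2L] + ext]
  nReal <- as.integer(sum(isReal))
  if (length(admissible)) {
    pts <- stemPoint(poly, admissible)
    d2 <- (pts[, 1L] - headEnd[[1L]])^2 + (pts[, 2L] - headEnd[[2L]])^2
    tbest <- admissible[[which.min(d2)]]
    pbest <- stemPoint(poly, tbest)
    return(new("IntersectionPoint", x = pbest[[1L]], y = pbest[[2L]],
               t = tbest, selection = "exact_root", nRealRoots = nReal))
  }
  # fallback: curve point of minimum distance to the ellipse boundary
  bnd <- ellipseBoundaryPoints(ellipse, n = 1440L)
  g <- function(t) {
    p <- stemPoint(poly, t)
    min(sqrt((bnd[, 1L] - p[[1L]])^2 + (bnd[, 2L] - p[[2L]])^2))
  }
  grid <- seq(dom[1L] - ext, dom[2L] + ext, length.out = 801L)
  gv <- vapply(grid, g, numeric(1L))
  i0 <- which.min(gv)
  lo <- grid[max(1L, i0 - 1L)]; hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(g, c(lo, hi))
  pbest <- stemPoint(poly, opt$minimum)
  new("IntersectionPoint", x = pbest[[1L]], y = pbest[[2L]],
      t = opt$minimum, selection = "closest_approach_fallback",
      nRealRoots = nReal)
}

#' Acute tilt angle from two slopes
#'
#' theta = arctan(|(kl - ks) / (1 + kl ks)|) in degrees, in [0, 90].
#' Perpendicular lines (1 + kl ks = 0) give 90. A vertical input
#' (\code{Inf}) uses the limit form arctan(|1/k|) against the other
#' slope; two vertical inputs are parallel and give 0.
#'
#' @param kl major-axis slope (or \code{Inf} for vertical).
#' @param ks tangent slope (or \code{Inf} for vertical).
#' @return angle in degrees, [0, 90].
#' @export
tiltAngleAcute <- function(kl, ks) {
  if (is.infinite(kl) && is.infinite(ks)) return(0)
  if (is.infinite(kl)) return(radToDeg(atan(abs(1 / ks))))
  if (is.infinite(ks)) return(radToDeg(atan(abs(1 / kl))))
  denom <- 1 + kl * ks
  if (denom == 0) return(90)
  radToDeg(atan(abs((kl - ks) / denom)))
}

#' Oriented tilt angle from two direction vectors
#'
#' theta = arccos(axis . tangent) in degrees, in [0, 180). The axis
#' direction is re-oriented toward increasing x (ties: increasing y)
#' before the product, matching the convention under which the
#' ground-truth angles are defined; the tangent direction is taken as
#' given and should point from the stem interior toward the intersection.
#' min(theta, 180 - theta) always equals the acute convention applied to
#' the corresponding slopes.
#'
#' @param axisDir numeric length-2, nonzero.
#' @param tangentDir numeric length-2, nonzero.
#' @return angle in degrees, [0, 180).
#' @export
tiltAngleOriented <- function(axisDir, tangentDir) {
  na <- sqrt(sum(axisDir^2)); nt <- sqrt(sum(tangentDir^2))
  if (na == 0 || nt == 0)
    diskTiltError("ZERO_VECTOR", "direction vectors must be nonzero")
  a <- axisDir / na
  if (a[[1L]] < 0 || (a[[1L]] == 0 && a[[2L]] < 0)) a <- -a
  d <- tangentDir / nt
  ang <- radToDeg(acos(clamp(sum(a * d), -1, 1)))
  if (ang >= 180) ang <- 0
  ang
}

# Drop centerline scanlines whose foreground runs are clipped and whose
# midpoints are therefore biased. Two clip sources: (a) scanlines abutting
# the head ellipse (the run ends at the head boundary rather than at the
# band edge) — dropped when the approximate distance to the ellipse
# boundary (|Q| / |grad Q| on the implicit form) is below clearFactor
# times the stem width; (b) scanlines at either end of a slanted band,
# whose runs are cut short — dropped when the run is much shorter than
# the median run. The trim is skipped when it would leave too few points
# for the fit; internal.
trimClippedScanlines <- function(centerline, stemMask, ellipse,
                                 clearFactor, order) {
  pts <- centerline@points
  grid <- stemMask@grid
  lens <- if (centerline@axis == "y-major") {
    vapply(pts[, 2L] + 1L, function(rr) longestRun(grid[rr, ]), numeric(1L))
  } else {
    vapply(pts[, 1L] + 1L, function(cc) longestRun(grid[, cc]), numeric(1L))
  }
  runW <- stats::median(lens)
  fullRun <- lens >= 0.75 * runW
  th <- ellipseThetaRad(ellipse)
  sa <- ellipse@a / 2; sb <- ellipse@b / 2
  dx <- pts[, 1L] - ellipse@h; dy <- pts[, 2L] - ellipse@k
  X <- cos(th) * dx + sin(th) * dy
  Y <- -sin(th) * dx + cos(th) * dy
  Q <- (X / sa)^2 + (Y / sb)^2 - 1
  gx <- 2 * (X * cos(th) / sa^2 - Y * sin(th) / sb^2)
  gy <- 2 * (X * sin(th) / sa^2 + Y * cos(th) / sb^2)
  d <- abs(Q) / pmax(sqrt(gx^2 + gy^2), 1e-12)
  keep <- d > clearFactor * runW & fullRun
  if (sum(keep) < max(order + 2L, 8L)) return(centerline)
  new("Centerline", points = pts[keep, , drop = FALSE],
      axis = centerline@axis)
}

# Oriented tangent direction of the stem model at parameter t, pointing
# from the stem interior toward the intersection; internal.
orientedTangentDir <- function(poly, t) {
  fp <- frameSlope(poly, t)
  d <- if (poly@frame == "x-major") c(1, fp) else c(fp, 1)
  sgn <- sign(t - mean(poly@domain))
  if (sgn == 0) sgn <- 1
  sgn * d / sqrt(sum(d^2))
}

#' Measure the tilt angle from a head and a stem mask
#'
#' The full pipeline: largest component of each mask; head contour and
#' stem centerline extraction; ellipse-constrained conic fit and major
#' axis; polynomial stem fit; stem-ellipse intersection; tangent slope at
#' the intersection; angle in the configured convention. The angle is
#' retained at full precision; round to 2 decimals for reporting.
#'
#' @param headMask,stemMask [BinaryMask-class] objects.
#' @param config a [tiltConfig()] list.
#' @return a [TiltMeasurement-class].
#' @export
measureTilt <- function(headMask, stemMask, config = tiltConfig()) {
  if (!any(headMask@grid == 1L))
    diskTiltError("EMPTY_HEAD", "head mask has no foreground")
  if (!any(stemMask@grid == 1L))
    diskTiltError("EMPTY_STEM", "stem mask has no foreground")
  contour <- extractOuterContour(headMask)
  pts <- contour@points
  if (config$contourStride > 1L)
    pts <- pts[seq(1L, nrow(pts), by = config$contourStride), , drop = FALSE]
  ellipse <- conicToEllipse(fitConic(pts))
  ax <- majorAxis(ellipse)
  stemMain <- largestComponent(stemMask)
  centerline <- extractCenterline(stemMain)
  notes <- character(0)
  if (config$headClearFactor > 0) {
    trimmed <- trimClippedScanlines(centerline, stemMain, ellipse,
                                    config$headClearFactor, config$order)
    if (nrow(trimmed@points) < nrow(centerline@points))
      notes <- c(notes, sprintf(
        "dropped %d head-clipped centerline scanlines",
        nrow(centerline@points) - nrow(trimmed@points)))
    centerline <- trimmed
  }
  poly <- fitStemPolynomial(centerline, config$order)
  ctr <- ellipseCenter(ellipse)
  ends <- centerline@points[c(1L, nrow(centerline@points)), , drop = FALSE]
  d2 <- (ends[, 1L] - ctr[[1L]])^2 + (ends[, 2L] - ctr[[2L]])^2
  headEnd <- ends[which.min(d2), ]
  ip <- intersectStemEllipse(poly, ellipse, headEnd,
                             rootExtend = config$rootExtend,
                             rootImagTol = config$rootImagTol)
  if (ip@selection == "closest_approach_fallback")
    notes <- c(notes, "intersection fell back to closest approach")
  # clamp the tangent evaluation into its (smaller) extrapolation margin
  dom <- poly@domain
  tmarg <- config$tangentExtend * diff(dom)
  tEval <- clamp(ip@t, dom[1L] - tmarg, dom[2L] + tmarg)
  if (tEval != ip@t)
    notes <- c(notes, sprintf("tangent evaluated at clamped t = %.3f", tEval))
  ks <- tangentSlope(poly, tEval, extend = config$tangentExtend)
  if (config$mode == "acute") {
    angle <- tiltAngleAcute(ax@kl, ks)
  } else {
    angle <- tiltAngleOriented(ax@v, orientedTangentDir(poly, tEval))
  }
  if (ip@selection == "exact_root") {
    res <- abs(ellipseImplicit(ellipse, ip@x, ip@y))
    if (res > config$onCurveTol)
      notes <- c(notes, sprintf("on-curve residual %.2e above tolerance", res))
  }
  new("TiltMeasurement", angleDeg = angle, angleMode = config$mode,
      kl = ax@kl, ks = ks, intersection = ip, ellipse = ellipse,
      stem = poly, diagnostics = notes)
}

#' Pair head instances with stem instances
#'
#' Greedy matching: repeatedly take the globally closest (head centroid,
#' stem end) pair among the unmatched instances; each stem is used at most
#' once. Surplus instances are reported unpaired.
#'
#' @param heads list of head [BinaryMask-class] objects.
#' @param stems list of stem [BinaryMask-class] objects.
#' @return list with \code{pairs} (data.frame head, stem, distance),
#'   \code{unpairedHeads}, \code{unpairedStems} (integer indices).
#' @export
pairInstances <- function(heads, stems) {
  if (!length(heads) || !length(stems))
    diskTiltError("EMPTY_LIST", "need at least one head and one stem")
  centroid <- function(m) {
    idx <- which(m@grid == 1L, arr.ind = TRUE)
    c(mean(idx[, 2L]) - 1, mean(idx[, 1L]) - 1)
  }
  stemEnds <- lapply(stems, function(s) {
    cl <- extractCenterline(largestComponent(s))
    cl@points[c(1L, nrow(cl@points)), , drop = FALSE]
  })
  hc <- lapply(heads, centroid)
  D <- matrix(Inf, length(heads), length(stems))
  for (i in seq_along(heads)) for (j in seq_along(stems)) {
    e <- stemEnds[[j]]
    D[i, j] <- sqrt(min((e[, 1L] - hc[[i]][[1L]])^2 +
                          (e[, 2L] - hc[[i]][[2L]])^2))
  }
  pairs <- data.frame(head = integer(0), stem = integer(0),
                      distance = numeric(0))
  Dw <- D
  while (any(is.finite(Dw))) {
    ij <- arrayInd(which.min(Dw), dim(Dw))
    pairs <- rbind(pairs, data.frame(head = ij[1L], stem = ij[2L],
                                     distance = Dw[ij]))
    Dw[ij[1L], ] <- Inf
    Dw[, ij[2L]] <- Inf
  }
  list(pairs = pairs,
       unpairedHeads = setdiff(seq_along(heads), pairs$head),
       unpairedStems = setdiff(seq_along(stems), pairs$stem))
}

#' @rdname asList
#' @export
setMethod("asList", "IntersectionPoint", function(x)
  list(x = x@x, y = x@y, t = x@t, selection = x@selection,
       n_real_roots = x@nRealRoots))

#' @rdname asList
#' @export
setMethod("asList", "TiltMeasurement", function(x)
  list(angle_deg = round(x@angleDeg, 2), mode = x@angleMode,
       kl = if (is.infinite(x@kl)) "vertical" else x@kl,
       ks = if (is.infinite(x@ks)) "vertical" else x@ks,
       intersection = asList(x@intersection),
       ellipse = asList(x@ellipse), stem = asList(x@stem),
       diagnostics = x@diagnostics))
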