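#' @import methods
NULL

#' BinaryMask: a single-class instance segmentation mask
#'
#' A 2-D foreground/background grid for one instance class. Rows index the
#' image y coordinate (top to bottom), columns the x coordinate (left to
#' right); pixel centers sit at integer coordinates with the top-left pixel
#' at (0, 0).
#'
#' @slot grid integer matrix of 0/1 values; rows = y, cols = x.
#' @slot classLabel character, one of \code{"head"} or \code{"stem"}.
#'
#' @seealso [readMask()], [largestComponent()], [extractOuterContour()],
#'   [extractCenterline()]
#' @export
setClass("BinaryMask",
  representation(grid = "matrix", classLabel = "character"))

setValidity("BinaryMask", function(object) {
  g <- object@grid
  if (nrow(g) < 1L || ncol(g) < 1L)
    return("mask must have height >= 1 and width >= 1")
  if (!all(g %in% c(0L, 1L)))
    return("every mask cell must be 0 or 1")
  if (length(object@classLabel) != 1L ||
      !object@classLabel %in% c("head", "stem"))
    return("classLabel must be \"head\" or \"stem\"")
  TRUE
})

#' Contour: an ordered boundary point sequence
#'
#' Points are (x, y) pixel coordinates. When traced from a mask, consecutive
#' points are 8-neighbors and the sequence is closed and clockwise, starting
#' from the topmost-then-leftmost boundary pixel.
#'
#' @slot points numeric matrix, n x 2, columns x and y.
#' @slot closed logical scalar.
#' @export
setClass("Contour",
  representation(points = "matrix", closed = "logical"))

setValidity("Contour", function(object) {
  p <- object@points
  if (ncol(p) != 2L) return("points must be an n x 2 matrix")
  if (nrow(p) < 1L) return("contour needs at least one point")
  if (anyNA(p)) return("contour points must be finite")
  TRUE
})

#' Centerline: per-scanline stem midpoints
#'
#' Ordered (x, y) midpoints of the longest foreground run on each scanline,
#' scanned along the dominant-extent axis of the stem mask. The independent
#' coordinate (y for \code{"y-major"}, x for \code{"x-major"}) is strictly
#' monotonic along the sequence.
#'
#' @slot points numeric matrix, n x 2, columns x and y.
#' @slot axis character, \code{"x-major"} or \code{"y-major"}.
#' @export
setClass("Centerline",
  representation(points = "matrix", axis = "character"))

setValidity("Centerline", function(object) {
  p <- object@points
  if (ncol(p) != 2L) return("points must be an n x 2 matrix")
  if (!object@axis %in% c("x-major", "y-major"))
    return("axis must be \"x-major\" or \"y-major\"")
  ind <- if (object@axis == "x-major") p[, 1L] else p[, 2L]
  if (nrow(p) > 1L && any(diff(ind) <= 0))
    return("independent coordinate must be strictly monotonic")
  TRUE
})

#' ConicCoefficients: general conic with the ellipse discriminant constraint
#'
#' Coefficients (A, B, C, D, E, F) of A x^2 + B x y + C y^2 + D x + E y + F
#' = 0, normalized so that 4AC - B^2 = 1 (which enforces the ellipse
#' condition 4AC - B^2 > 0) and A > 0.
#'
#' @slot coef named numeric of length 6 (A, B, C, D, E, F).
#' @export
setClass("ConicCoefficients", representation(coef = "numeric"))

setValidity("ConicCoefficients", function(object) {
  co <- object@coef
  if (length(co) != 6L || anyNA(co)) return("coef must be 6 finite numbers")
  disc <- 4 * co[[1L]] * co[[3L]] - co[[2L]]^2
  if (disc <= 0) return("4AC - B^2 must be > 0 (ellipse condition)")
  if (abs(disc - 1) > 1e-6) return("conic must be normalized to 4AC - B^2 = 1")
  TRUE
})

#' EllipseParams: standard-form ellipse for the head boundary
#'
#' Center (h, k), full axis lengths a >= b (a is the full major-axis length;
#' the semi-axes are a/2 and b/2), and major-axis rotation theta in degrees,
#' normalized to (-90, 90].
#'
#' @slot h,k numeric center coordinates (px).
#' @slot a,b numeric full major/minor axis lengths (px), a >= b > 0.
#' @slot thetaDeg numeric rotation of the major axis from +x, degrees.
#' @export
setClass("EllipseParams",
  representation(h = "numeric", k = "numeric", a = "numeric", b = "numeric",
                 thetaDeg = "numeric"))

setValidity("EllipseParams", function(object) {
  v <- c(object@h, object@k, object@a, object@b, object@thetaDeg)
  if (length(v) != 5L || anyNA(v) || any(!is.finite(v)))
    return("all ellipse parameters must be finite scalars")
  if (!(object@a >= object@b && object@b > 0))
    return("need a >= b > 0")
  if (!(object@thetaDeg > -90 && object@thetaDeg <= 90))
    return("thetaDeg must lie in (-90, 90]")
  TRUE
})

#' MajorAxis: the head's major-axis line
#'
#' Unit direction vector, slope (or vertical flag), the two endpoints at
#' distance a/2 from the center, and the intercept of y = kl x + cl when the
#' axis is not vertical.
#'
#' @slot v numeric length-2 unit direction (cos theta, sin theta).
#' @slot kl numeric slope; \code{Inf} when vertical.
#' @slot p1,p2 numeric length-2 endpoints.
#' @slot cl numeric intercept; \code{NA} when vertical.
#' @slot vertical logical flag.
#' @export
setClass("MajorAxis",
  representation(v = "numeric", kl = "numeric", p1 = "numeric",
                 p2 = "numeric", cl = "numeric", vertical = "logical"))

setValidity("MajorAxis", function(object) {
  if (abs(sqrt(sum(object@v^2)) - 1) > 1e-9)
    return("direction vector must have unit length")
  if (length(object@p1) != 2L || length(object@p2) != 2L)
    return("endpoints must be length-2")
  TRUE
})

#' StemPolynomial: polynomial stem centerline model
#'
#' f(t) = a0 + a1 t + a2 t^2 + a3 t^3 + a4 t^4 in the fitting frame: for an
#' \code{"x-major"} frame y = f(x); for \code{"y-major"} x = f(y).
#' Coefficients above the fitted order are exactly zero.
#'
#' @slot coeffs numeric length 5 (a0..a4); entries beyond \code{order} are 0.
#' @slot order integer, 2, 3 or 4.
#' @slot frame character, \code{"x-major"} or \code{"y-major"}.
#' @slot domain numeric length-2 range of the independent coordinate.
#' @slot rss numeric residual sum of squares of the least-squares fit.
#' @export
setClass("StemPolynomial",
  representation(coeffs = "numeric", order = "integer", frame = "character",
                 domain = "numeric", rss = "numeric"))

setValidity("StemPolynomial", function(object) {
  if (length(object@coeffs) != 5L || anyNA(object@coeffs))
    return("coeffs must be 5 finite numbers (a0..a4)")
  if (!object@order %in% 2:4) return("order must be 2, 3 or 4")
  if (object@order < 4L && any(object@coeffs[(object@order + 2L):5L] != 0))
    return("coefficients beyond the order must be exactly 0")
  if (!object@frame %in% c("x-major", "y-major"))
    return("frame must be \"x-major\" or \"y-major\"")
  if (length(object@domain) != 2L || !(object@domain[1L] < object@domain[2L]))
    return("domain must be a non-degenerate [t_min, t_max]")
  if (object@rss < 0) return("rss must be >= 0")
  TRUE
})

#' OrderDiagnostics: residual comparison across polynomial orders
#'
#' @slot rss named numeric of per-order residual sums of squares.
#' @slot selectedOrder integer order chosen by the stopping rule.
#' @export
setClass("OrderDiagnostics",
  representation(rss = "numeric", selectedOrder = "integer"))

#' IntersectionPoint: where the stem curve meets the head ellipse
#'
#' @slot x,y numeric pixel coordinates.
#' @slot t numeric independent-coordinate value on the stem polynomial.
#' @slot selection character, \code{"exact_root"} or
#'   \code{"closest_approach_fallback"}.
#' @slot nRealRoots integer count of admissible real roots.
#' @export
setClass("IntersectionPoint",
  representation(x = "numeric", y = "numeric", t = "numeric",
                 selection = "character", nRealRoots = "integer"))

setValidity("IntersectionPoint", function(object) {
  if (!object@selection %in% c("exact_root", "closest_approach_fallback"))
    return("unknown selection mode")
  TRUE
})

#' TiltMeasurement: the full mask-to-angle result
#'
#' @slot angleDeg numeric tilt angle in degrees (full precision; round to 2
#'   decimals for reporting).
#' @slot angleMode character, \code{"oriented"} ([0, 180)) or
#'   \code{"acute"} ([0, 90]).
#' @slot kl numeric major-axis slope (\code{Inf} = vertical).
#' @slot ks numeric stem tangent slope at the intersection (\code{Inf} =
#'   vertical).
#' @slot intersection an [IntersectionPoint-class].
#' @slot ellipse an [EllipseParams-class].
#' @slot stem a [StemPolynomial-class].
#' @slot diagnostics character notes.
#' @export
setClass("TiltMeasurement",
  representation(angleDeg = "numeric", angleMode = "character",
                 kl = "numeric", ks = "numeric",
                 intersection = "IntersectionPoint",
                 ellipse = "EllipseParams", stem = "StemPolynomial",
                 diagnostics = "character"))

setValidity("TiltMeasurement", function(object) {
  if (!object@angleMode %in% c("oriented", "acute"))
    return("angleMode must be \"oriented\" or \"acute\"")
  if (object@angleMode == "acute" &&
      (object@angleDeg < 0 || object@angleDeg > 90))
    return("acute angle must lie in [0, 90]")
  if (object@angleMode == "oriented" &&
      (object@angleDeg < 0 || object@angleDeg >= 180))
    return("oriented angle must lie in [0, 180)")
  TRUE
})

#' SceneParams: generating parameters of one synthetic scene
#'
#' Everything needed to rasterize a ground-truth scene deterministically:
#' the head ellipse, the stem polynomial (y-major by default: stems grow
#' downward from the head in image coordinates), the band width, the
#' boundary jitter scale and the seed. \code{trueAngleDeg} is the analytic
#' oriented angle, recomputable from the geometry alone;
#' \code{trueAcuteDeg} = min(theta, 180 - theta) for the acute convention.
#'
#' @slot imageSize integer length-2 (height, width) px.
#' @slot ellipse an [EllipseParams-class].
#' @slot stemCoeffs numeric length 5 (a0..a4) in the stem frame.
#' @slot stemFrame character, \code{"x-major"} or \code{"y-major"}.
#' @slot stemDomain numeric length-2 range of the independent coordinate.
#' @slot bandWidthPx numeric perpendicular stem band width.
#' @slot trueAngleDeg,trueAcuteDeg numeric ground-truth angles.
#' @slot jitterPx numeric boundary perturbation scale (0 = none).
#' @slot seed integer RNG seed for the jitter.
#' @export
setClass("SceneParams",
  representation(imageSize = "integer", ellipse = "EllipseParams",
                 stemCoeffs = "numeric", stemFrame = "character",
                 stemDomain = "numeric", bandWidthPx = "numeric",
                 trueAngleDeg = "numeric", trueAcuteDeg = "numeric",
                 jitterPx = "numeric", seed = "integer"))

setValidity("SceneParams", function(object) {
  if (length(object@imageSize) != 2L || any(object@imageSize < 8L))
    return("imageSize must be two integers >= 8")
  if (length(object@stemCoeffs) != 5L) return("stemCoeffs must be a0..a4")
  if (!object@stemFrame %in% c("x-major", "y-major"))
    return("stemFrame must be \"x-major\" or \"y-major\"")
  if (object@bandWidthPx <= 0) return("bandWidthPx must be > 0")
  if (object@jitterPx < 0) return("jitterPx must be >= 0")
  TRUE
})

#' AugmentationConfig: brightness / rotation / noise augmentation ranges
#'
#' Defaults match the augmentation scheme the segmentation training used:
#' brightness adjusted randomly in -50\% to +50\%, rotation in -90 to +90
#' degrees, additive zero-mean Gaussian noise with standard deviation drawn
#' in 0--20\% of the full intensity scale.
#'
#' @slot brightnessRange numeric length-2 fraction range, within [-0.5, 0.5].
#' @slot rotationRange numeric length-2 degree range, within [-90, 90].
#' @slot noiseRange numeric length-2 noise-sd fraction range, within [0, 0.2].
#' @slot seed integer RNG seed.
#' @export
setClass("AugmentationConfig",
  representation(brightnessRange = "numeric", rotationRange = "numeric",
                 noiseRange = "numeric", seed = "integer"))

setValidity("AugmentationConfig", function(object) {
  chk <- function(r, lo, hi) length(r) == 2L && r[1L] <= r[2L] &&
    r[1L] >= lo && r[2L] <= hi
  if (!chk(object@brightnessRange, -0.5, 0.5))
    return("brightnessRange must lie within [-0.5, 0.5]")
  if (!chk(object@rotationRange, -90, 90))
    return("rotationRange must lie within [-90, 90]")
  if (!chk(object@noiseRange, 0, 0.2))
    return("noiseRange must lie within [0, 0.2]")
  TRUE
})

#' MetricsReport: angle-prediction evaluation statistics
#'
#' RMSE, MAE and R-squared of predicted vs. reference angles, plus the
#' error-distribution summaries (sample standard deviation and
#' Fisher-Pearson skewness of predicted - actual) and optional per-interval
#' sub-reports.
#'
#' @slot n integer number of records.
#' @slot rmseDeg,maeDeg numeric error statistics (degrees).
#' @slot r2 numeric coefficient of determination; \code{NA} when the
#'   reference angles are constant.
#' @slot meanActualDeg numeric mean of the reference angles.
#' @slot errorSd numeric sample (n-1) SD of the errors.
#' @slot errorSkewness numeric Fisher-Pearson g1 of the errors.
#' @slot intervals list of per-interval sub-reports (possibly empty).
#' @export
setClass("MetricsReport",
  representation(n = "integer", rmseDeg = "numeric", maeDeg = "numeric",
                 r2 = "numeric", meanActualDeg = "numeric",
                 errorSd = "numeric", errorSkewness = "numeric",
                 intervals = "list"))
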