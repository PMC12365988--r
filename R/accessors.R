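# Accessor generics and show methods for the core classes.

#' @rdname BinaryMask-class
#' @param object,x a package object.
#' @export
setGeneric("maskGrid", function(x) standardGeneric("maskGrid"))

#' @rdname BinaryMask-class
#' @export
setMethod("maskGrid", "BinaryMask", function(x) x@grid)

#' @rdname BinaryMask-class
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' @rdname BinaryMask-class
#' @export
setMethod("classLabel", "BinaryMask", function(x) x@classLabel)

#' @rdname BinaryMask-class
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@grid))

#' Ordered point matrix of a Contour or Centerline
#'
#' @param x a [Contour-class] or [Centerline-class].
#' @return numeric n x 2 matrix with columns \code{x}, \code{y}.
#' @export
setGeneric("coordPoints", function(x) standardGeneric("coordPoints"))

#' @rdname coordPoints
#' @export
setMethod("coordPoints", "Contour", function(x) x@points)

#' @rdname coordPoints
#' @export
setMethod("coordPoints", "Centerline", function(x) x@points)

#' @rdname Centerline-class
#' @param x a [Centerline-class].
#' @export
setGeneric("scanAxis", function(x) standardGeneric("scanAxis"))

#' @rdname Centerline-class
#' @export
setMethod("scanAxis", "Centerline", function(x) x@axis)

#' @rdname ConicCoefficients-class
#' @param x a [ConicCoefficients-class].
#' @export
setGeneric("conicCoef", function(x) standardGeneric("conicCoef"))

#' @rdname ConicCoefficients-class
#' @export
setMethod("conicCoef", "ConicCoefficients", function(x) x@coef)

#' EllipseParams accessors
#'
#' @param x an [EllipseParams-class].
#' @return \code{ellipseCenter}: numeric (h, k); \code{ellipseAxes}: numeric
#'   (a, b) full lengths; \code{ellipseTheta}: rotation in degrees;
#'   \code{ellipseThetaRad}: the same in radians.
#' @export
setGeneric("ellipseCenter", function(x) standardGeneric("ellipseCenter"))

#' @rdname ellipseCenter
#' @export
setMethod("ellipseCenter", "EllipseParams", function(x) c(h = x@h, k = x@k))

#' @rdname ellipseCenter
#' @export
setGeneric("ellipseAxes", function(x) standardGeneric("ellipseAxes"))

#' @rdname ellipseCenter
#' @export
setMethod("ellipseAxes", "EllipseParams", function(x) c(a = x@a, b = x@b))

#' @rdname ellipseCenter
#' @export
setGeneric("ellipseTheta", function(x) standardGeneric("ellipseTheta"))

#' @rdname ellipseCenter
#' @export
setMethod("ellipseTheta", "EllipseParams", function(x) x@thetaDeg)

#' @rdname ellipseCenter
#' @export
setGeneric("ellipseThetaRad", function(x) standardGeneric("ellipseThetaRad"))

#' @rdname ellipseCenter
#' @export
setMethod("ellipseThetaRad", "EllipseParams",
  function(x) x@thetaDeg * pi / 180)

#' StemPolynomial accessors
#'
#' @param x a [StemPolynomial-class].
#' @export
setGeneric("stemCoeffs", function(x) standardGeneric("stemCoeffs"))

#' @rdname stemCoeffs
#' @export
setMethod("stemCoeffs", "StemPolynomial", function(x) x@coeffs)

#' @rdname stemCoeffs
#' @export
setGeneric("stemOrder", function(x) standardGeneric("stemOrder"))

#' @rdname stemCoeffs
#' @export
setMethod("stemOrder", "StemPolynomial", function(x) x@order)

#' @rdname stemCoeffs
#' @export
setGeneric("stemFrame", function(x) standardGeneric("stemFrame"))

#' @rdname stemCoeffs
#' @export
setMethod("stemFrame", "StemPolynomial", function(x) x@frame)

#' @rdname stemCoeffs
#' @export
setGeneric("stemDomain", function(x) standardGeneric("stemDomain"))

#' @rdname stemCoeffs
#' @export
setMethod("stemDomain", "StemPolynomial", function(x) x@domain)

#' @rdname stemCoeffs
#' @export
setGeneric("stemRss", function(x) standardGeneric("stemRss"))

#' @rdname stemCoeffs
#' @export
setMethod("stemRss", "StemPolynomial", function(x) x@rss)

#' TiltMeasurement accessors
#'
#' @param x a [TiltMeasurement-class].
#' @export
setGeneric("angleDeg", function(x) standardGeneric("angleDeg"))

#' @rdname angleDeg
#' @export
setMethod("angleDeg", "TiltMeasurement", function(x) x@angleDeg)

#' @rdname angleDeg
#' @export
setGeneric("angleMode", function(x) standardGeneric("angleMode"))

#' @rdname angleDeg
#' @export
setMethod("angleMode", "TiltMeasurement", function(x) x@angleMode)

#' @rdname angleDeg
#' @export
setGeneric("tiltEllipse", function(x) standardGeneric("tiltEllipse"))

#' @rdname angleDeg
#' @export
setMethod("tiltEllipse", "TiltMeasurement", function(x) x@ellipse)

#' @rdname angleDeg
#' @export
setGeneric("tiltStem", function(x) standardGeneric("tiltStem"))

#' @rdname angleDeg
#' @export
setMethod("tiltStem", "TiltMeasurement", function(x) x@stem)

#' @rdname angleDeg
#' @export
setGeneric("tiltIntersection", function(x) standardGeneric("tiltIntersection"))

#' @rdname angleDeg
#' @export
setMethod("tiltIntersection", "TiltMeasurement", function(x) x@intersection)

#' SceneParams accessors
#'
#' @param x a [SceneParams-class].
#' @export
setGeneric("trueAngleDeg", function(x) standardGeneric("trueAngleDeg"))

#' @rdname trueAngleDeg
#' @export
setMethod("trueAngleDeg", "SceneParams", function(x) x@trueAngleDeg)

#' @rdname trueAngleDeg
#' @export
setGeneric("trueAcuteDeg", function(x) standardGeneric("trueAcuteDeg"))

#' @rdname trueAngleDeg
#' @export
setMethod("trueAcuteDeg", "SceneParams", function(x) x@trueAcuteDeg)

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask [%s] %d x %d px, %d foreground px\n",
              object@classLabel, nrow(object@grid), ncol(object@grid),
              sum(object@grid)))
})

setMethod("show", "Contour", function(object) {
  cat(sprintf("Contour with %d points (%s)\n", nrow(object@points),
              if (object@closed) "closed" else "open"))
})

setMethod("show", "Centerline", function(object) {
  cat(sprintf("Centerline with %d points, %s scan\n",
              nrow(object@points), object@axis))
})

setMethod("show", "ConicCoefficients", function(object) {
  cat("ConicCoefficients (4AC - B^2 = 1):\n")
  print(round(object@coef, 6))
})

setMethod("show", "EllipseParams", function(object) {
  cat(sprintf(
    "EllipseParams: center (%.2f, %.2f), axes a=%.2f b=%.2f, theta=%.2f deg\n",
    object@h, object@k, object@a, object@b, object@thetaDeg))
})

setMethod("show", "MajorAxis", function(object) {
  cat(sprintf("MajorAxis: v=(%.4f, %.4f), %s, endpoints (%.2f, %.2f)-(%.2f, %.2f)\n",
              object@v[1L], object@v[2L],
              if (object@vertical) "vertical" else sprintf("slope %.4f", object@kl),
              object@p1[1L], object@p1[2L], object@p2[1L], object@p2[2L]))
})

setMethod("show", "StemPolynomial", function(object) {
  cat(sprintf(
    "StemPolynomial order %d (%s), domain [%.1f, %.1f], rss %.4g\n",
    object@order, object@frame, object@domain[1L], object@domain[2L],
    object@rss))
})

setMethod("show", "OrderDiagnostics", function(object) {
  cat("OrderDiagnostics: selected order", object@selectedOrder, "\n")
  print(object@rss)
})

setMethod("show", "IntersectionPoint", function(object) {
  cat(sprintf("IntersectionPoint (%.2f, %.2f) at t=%.2f [%s, %d real roots]\n",
              object@x, object@y, object@t, object@selection,
              object@nRealRoots))
})

setMethod("show", "TiltMeasurement", function(object) {
  cat(sprintf("TiltMeasurement: %.2f deg (%s mode)\n",
              round(object@angleDeg, 2), object@angleMode))
  show(object@ellipse)
  show(object@stem)
  show(object@intersection)
})

setMethod("show", "SceneParams", function(object) {
  cat(sprintf(
    "SceneParams %dx%d px, true angle %.2f deg (acute %.2f), jitter %.1f px, seed %d\n",
    object@imageSize[1L], object@imageSize[2L], object@trueAngleDeg,
    object@trueAcuteDeg, object@jitterPx, object@seed))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: n=%d RMSE=%.4f MAE=%.4f R2=%s\n",
              object@n, object@rmseDeg, object@maeDeg,
              if (is.na(object@r2)) "NA (constant actuals)"
              else sprintf("%.4f", object@r2)))
  if (length(object@intervals))
    cat("  with", length(object@intervals), "interval sub-reports\n")
})
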