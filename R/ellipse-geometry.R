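# Ellipse-specific conic least squares and conversion to standard form.
#
# The head boundary is modeled as the general conic
#   A x^2 + B x y + C y^2 + D x + E y + F = 0,
# fitted by minimizing the algebraic residual sum over the boundary samples
# subject to the discriminant constraint 4AC - B^2 = 1. The constraint
# makes the quadratic part elliptic by construction (a hyperbola or
# parabola can never be returned) and removes the trivial all-zero
# solution that unconstrained algebraic least squares admits. The solver
# is the direct ellipse-specific least squares method in its numerically
# stable block form (scatter-matrix partitioning + 3x3 eigenproblem),
# with the data centered at its mean for conditioning and the conic
# translated back afterwards.

#' Fit an ellipse-constrained conic to boundary points
#'
#' @param points numeric n x 2 matrix of (x, y) boundary samples, n >= 6,
#'   not all collinear.
#' @return a [ConicCoefficients-class], normalized to 4AC - B^2 = 1 with
#'   A > 0.
#' @export
fitConic <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 6L)
    diskTiltError("TOO_FEW_POINTS",
                  sprintf("conic fit needs >= 6 points, got %d", nrow(points)))
  x0 <- points[, 1L]; y0 <- points[, 2L]
  mx <- mean(x0); my <- mean(y0)
  x <- x0 - mx; y <- y0 - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm))
    diskTiltError("DEGENERATE_POINTS",
                  "degenerate point configuration (collinear or coincident)")
  M <- S1 + S2 %*% Tm
  # premultiply by inv of the constraint matrix [[0,0,2],[0,-1,0],[2,0,0]]
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1L, ] * V[3L, ] - V[2L, ]^2
  ok <- which(cond > 1e-12)
  if (!length(ok))
    diskTiltError("DEGENERATE_POINTS",
                  "no ellipse solution exists for these points")
  a1 <- V[, ok[1L]]
  a2 <- as.vector(Tm %*% a1)
  A <- a1[1L]; B <- a1[2L]; C <- a1[3L]
  D <- a2[1L]; E <- a2[2L]; Fc <- a2[3L]
  # undo the centering: substitute x -> x - mx, y -> y - my
  Dn <- D - 2 * A * mx - B * my
  En <- E - B * mx - 2 * C * my
  Fn <- Fc + A * mx^2 + B * mx * my + C * my^2 - D * mx - E * my
  co <- c(A = A, B = B, C = C, D = Dn, E = En, F = Fn)
  if (co[["A"]] < 0) co <- -co
  co <- co / sqrt(4 * co[["A"]] * co[["C"]] - co[["B"]]^2)
  new("ConicCoefficients", coef = co)
}

#' Algebraic residual of a conic on a point set
#'
#' Mean squared value of A x^2 + B x y + C y^2 + D x + E y + F over the
#' points; the quantity the constrained fit minimizes (up to the fixed
#' normalization).
#'
#' @param conic a [ConicCoefficients-class] (or a length-6 numeric).
#' @param points numeric n x 2 matrix.
#' @return mean squared algebraic residual.
#' @export
conicResidual <- function(conic, points) {
  co <- if (is(conic, "ConicCoefficients")) conic@coef else conic
  x <- points[, 1L]; y <- points[, 2L]
  mean((co[[1L]] * x^2 + co[[2L]] * x * y + co[[3L]] * y^2 +
          co[[4L]] * x + co[[5L]] * y + co[[6L]])^2)
}

#' Convert a conic to standard ellipse parameters
#'
#' The center solves the stationarity system 2Ah + Bk + D = 0,
#' Bh + 2Ck + E = 0; axis lengths and rotation come from the
#' eigen-structure of the quadratic part. The rotation follows
#' theta = arctan(B / (A - C)) / 2 with the quadrant fixed so theta is the
#' direction of the major axis, normalized to (-90, 90]; a circle gets
#' theta = 0 by convention. Axis lengths are stored as full lengths (the
#' semi-axes are a/2, b/2).
#'
#' @param conic a [ConicCoefficients-class].
#' @return an [EllipseParams-class].
#' @export
conicToEllipse <- function(conic) {
  co <- conic@coef
  A <- co[[1L]]; B <- co[[2L]]; C <- co[[3L]]
  D <- co[[4L]]; E <- co[[5L]]; Fc <- co[[6L]]
  disc <- 4 * A * C - B^2
  if (disc <= 0)
    diskTiltError("NOT_AN_ELLIPSE", "4AC - B^2 must be > 0")
  ctr <- solve(matrix(c(2 * A, B, B, 2 * C), 2L, 2L), c(-D, -E))
  h <- ctr[[1L]]; k <- ctr[[2L]]
  F0 <- A * h^2 + B * h * k + C * k^2 + D * h + E * k + Fc
  M <- matrix(c(A, B / 2, B / 2, C), 2L, 2L)
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values  # decreasing
  semis <- -F0 / lam
  if (any(semis <= 0))
    diskTiltError("IMAGINARY_ELLIPSE",
                  "conic has no real boundary (imaginary or point ellipse)")
  semiMinor <- sqrt(semis[[1L]])   # larger eigenvalue -> shorter axis
  semiMajor <- sqrt(semis[[2L]])
  if (abs(B) < 1e-12 && abs(A - C) < 1e-12 * max(abs(A), abs(C))) {
    theta <- 0                     # circle: rotation undefined, fix at 0
  } else {
    theta <- 0.5 * atan2(B, A - C)
    # q(theta) = value of the quadratic form along (cos, sin); the major
    # axis direction belongs to the smaller eigenvalue
    q <- A * cos(theta)^2 + B * cos(theta) * sin(theta) + C * sin(theta)^2
    if (abs(q - lam[[1L]]) < abs(q - lam[[2L]])) theta <- theta + pi / 2
  }
  thetaDeg <- radToDeg(theta)
  thetaDeg <- ((thetaDeg + 90) %% 180) - 90          # to (-90, 90]
  if (thetaDeg == -90) thetaDeg <- 90
  new("EllipseParams", h = h, k = k,
      a = 2 * semiMajor, b = 2 * semiMinor, thetaDeg = thetaDeg)
}

#' Major-axis line of an ellipse
#'
#' Direction vector (cos theta, sin theta), slope (or vertical flag with
#' the line x = h), the two endpoints offset by a/2 from the center along
#' the direction, and the intercept of y = kl x + cl when not vertical.
#'
#' @param ellipse an [EllipseParams-class].
#' @return a [MajorAxis-class].
#' @export
majorAxis <- function(ellipse) {
  th <- ellipseThetaRad(ellipse)
  v <- c(cos(th), sin(th))
  vertical <- abs(ellipse@thetaDeg - 90) < 1e-9
  half <- ellipse@a / 2
  p1 <- c(ellipse@h + half * v[[1L]], ellipse@k + half * v[[2L]])
  p2 <- c(ellipse@h - half * v[[1L]], ellipse@k - half * v[[2L]])
  if (vertical) {
    new("MajorAxis", v = c(0, 1), kl = Inf, p1 = p1, p2 = p2,
        cl = NA_real_, vertical = TRUE)
  } else {
    kl <- tan(th)
    new("MajorAxis", v = v, kl = kl, p1 = p1, p2 = p2,
        cl = ellipse@k - kl * ellipse@h, vertical = FALSE)
  }
}

#' Sample points on an ellipse boundary
#'
#' @param ellipse an [EllipseParams-class].
#' @param n number of points.
#' @param phi optional parametric angles (radians); overrides \code{n}.
#' @return numeric n x 2 matrix of (x, y) boundary points.
#' @export
ellipseBoundaryPoints <- function(ellipse, n = 64L, phi = NULL) {
  if (is.null(phi)) phi <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  th <- ellipseThetaRad(ellipse)
  sa <- ellipse@a / 2; sb <- ellipse@b / 2
  xr <- sa * cos(phi); yr <- sb * sin(phi)
  cbind(x = ellipse@h + xr * cos(th) - yr * sin(th),
        y = ellipse@k + xr * sin(th) + yr * cos(th))
}

#' Implicit ellipse value in normalized coordinates
#'
#' Evaluates (X/sa)^2 + (Y/sb)^2 - 1 where (X, Y) are the point
#' coordinates in the ellipse-aligned frame; zero on the boundary,
#' negative inside.
#'
#' @param ellipse an [EllipseParams-class].
#' @param x,y point coordinates (vectorized).
#' @return numeric vector of implicit values.
#' @export
ellipseImplicit <- function(ellipse, x, y) {
  th <- ellipseThetaRad(ellipse)
  sa <- ellipse@a / 2; sb <- ellipse@b / 2
  dx <- x - ellipse@h; dy <- y - ellipse@k
  X <- cos(th) * dx + sin(th) * dy
  Y <- -sin(th) * dx + cos(th) * dy
  (X / sa)^2 + (Y / sb)^2 - 1
}

#' Serializable list form of package objects
#'
#' @param x an [EllipseParams-class], [StemPolynomial-class],
#'   [IntersectionPoint-class] or [TiltMeasurement-class].
#' @return a plain list suitable for \code{jsonlite::toJSON}.
#' @export
setGeneric("asList", function(x) standardGeneric("asList"))

#' @rdname asList
#' @export
setMethod("asList", "EllipseParams", function(x)
  list(h = x@h, k = x@k, a = x@a, b = x@b, theta_deg = x@thetaDeg))
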