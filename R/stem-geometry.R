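# Polynomial stem centerline models, order comparison, tangent slopes.
#
# The centerline is modeled as f(t) = a0 + a1 t + a2 t^2 + a3 t^3 (order 3
# by default; orders 2 and 4 are available for diagnostics), with the
# coefficients minimizing the residual sum of squares over the centerline
# points. The fit happens in the frame recorded by the centerline: y = f(x)
# for an x-major scan, x = f(y) for a y-major scan. Writing the model as
# a function of the dominant coordinate keeps the problem well posed for
# near-vertical stems; slopes are mapped back to the image dy/dx frame
# only at tangent evaluation.

.fitPolyLS <- function(tt, vv, order) {
  keepT <- unique(tt)
  if (length(keepT) < order + 1L)
    diskTiltError("TOO_FEW_POINTS", sprintf(
      "order-%d fit needs >= %d distinct abscissae, got %d",
      order, order + 1L, length(keepT)))
  # center and scale the abscissa to [-1, 1] for conditioning, solve the
  # least squares there, then expand back to raw-coordinate coefficients
  tm <- (max(tt) + min(tt)) / 2
  hw <- (max(tt) - min(tt)) / 2
  u <- (tt - tm) / hw
  U <- outer(u, 0:order, `^`)
  qrU <- qr(U)
  if (qrU$rank < order + 1L)
    diskTiltError("RANK_DEFICIENT", "rank-deficient design for this order")
  cu <- qr.coef(qrU, vv)
  rss <- sum((vv - U %*% cu)^2)
  # compose with u = (t - tm)/hw: coefficients of sum_j cu_j * (alpha t + beta)^j
  alpha <- 1 / hw; beta <- -tm / hw
  coeffs <- c(cu[[1L]])
  lin <- c(beta, alpha)
  pw <- 1
  for (j in seq_len(order)) {
    pw <- polyMul(pw, lin)
    coeffs <- polyAdd(coeffs, cu[[j + 1L]] * pw)
  }
  list(coeffs = coeffs, rss = rss)
}

#' Fit a polynomial model to a stem centerline
#'
#' Ordinary least squares in the centerline's fitting frame. The stored
#' \code{rss} equals the minimized sum of squared residuals.
#'
#' @param centerline a [Centerline-class].
#' @param order polynomial order, 2, 3 (default) or 4.
#' @return a [StemPolynomial-class].
#' @export
fitStemPolynomial <- function(centerline, order = 3L) {
  order <- as.integer(order)
  if (!order %in% 2:4)
    diskTiltError("BAD_ORDER", "order must be 2, 3 or 4")
  p <- centerline@points
  if (centerline@axis == "x-major") {
    tt <- p[, 1L]; vv <- p[, 2L]
  } else {
    tt <- p[, 2L]; vv <- p[, 1L]
  }
  fit <- .fitPolyLS(tt, vv, order)
  coeffs <- rep(0, 5)
  coeffs[seq_along(fit$coeffs)] <- fit$coeffs
  if (order < 4L) coeffs[(order + 2L):5L] <- 0
  new("StemPolynomial", coeffs = coeffs, order = order,
      frame = centerline@axis, domain = range(tt), rss = fit$rss)
}

#' Compare polynomial orders on one centerline
#'
#' Fits each candidate order and selects the smallest order whose relative
#' residual improvement over the next order falls below \code{tolRel}:
#' increasing the order stops paying once the extra flexibility buys less
#' than a \code{tolRel} fraction of the residual. Residuals are
#' non-increasing in the order (nested least squares). The measurement
#' pipeline keeps order 3 fixed; this is a diagnostic.
#'
#' @param centerline a [Centerline-class].
#' @param orders increasing candidate orders.
#' @param tolRel relative-improvement stopping tolerance (default 0.05).
#' @return an [OrderDiagnostics-class].
#' @export
compareOrders <- function(centerline, orders = c(2L, 3L, 4L), tolRel = 0.05) {
  orders <- sort(as.integer(orders))
  fits <- lapply(orders, function(o) fitStemPolynomial(centerline, o))
  rss <- vapply(fits, stemRss, numeric(1L))
  names(rss) <- paste0("order", orders)
  sel <- orders[[length(orders)]]
  for (i in seq_len(length(orders) - 1L)) {
    gain <- if (rss[[i]] <= .Machine$double.eps) 0
      else (rss[[i]] - rss[[i + 1L]]) / rss[[i]]
    if (gain < tolRel) { sel <- orders[[i]]; break }
  }
  new("OrderDiagnostics", rss = rss, selectedOrder = as.integer(sel))
}

#' Tangent slope of the stem model in the image frame
#'
#' Evaluates the first derivative f'(t) of the fitted polynomial at t in
#' the fitting frame. For an x-major frame this is already the image dy/dx
#' slope; for a y-major frame (x = f(y)) the image slope is 1/f'(t), with
#' \code{Inf} returned as the vertical-direction flag when |f'(t)| <
#' 1e-12 (the stem locally parallel to the image y axis).
#'
#' @param poly a [StemPolynomial-class].
#' @param t independent coordinate; must lie within the fitting domain
#'   extended by at most \code{extend} of its length on each side.
#' @param extend allowed relative extrapolation margin (default 0.10).
#' @return image-frame slope (\code{Inf} = vertical).
#' @export
tangentSlope <- function(poly, t, extend = 0.10) {
  dom <- poly@domain
  margin <- extend * diff(dom)
  if (t < dom[1L] - margin || t > dom[2L] + margin)
    diskTiltError("OUT_OF_DOMAIN", sprintf(
      "t = %.3f outside domain [%.3f, %.3f] + %.0f%% margin",
      t, dom[1L], dom[2L], 100 * extend))
  fp <- polyEval(polyDeriv(poly@coeffs), t)
  if (poly@frame == "x-major") return(fp)
  if (abs(fp) < 1e-12) return(Inf)
  1 / fp
}

# Derivative in the fitting frame (no image-frame conversion); internal.
frameSlope <- function(poly, t) polyEval(polyDeriv(poly@coeffs), t)

# Evaluate the stem model point (x, y) at parameter t; internal.
stemPoint <- function(poly, t) {
  v <- polyEval(poly@coeffs, t)
  if (poly@frame == "x-major") cbind(x = t, y = v) else cbind(x = v, y = t)
}

#' @rdname asList
#' @export
setMethod("asList", "StemPolynomial", function(x)
  list(coeffs = as.numeric(x@coeffs), order = x@order, frame = x@frame,
       domain = as.numeric(x@domain), rss = x@rss))
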