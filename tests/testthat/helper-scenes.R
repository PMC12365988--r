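# Shared fixture builders. Everything is generated in code; no binary
# fixtures.

# Binary mask straight from a 0/1 matrix.
mkMask <- function(grid, label = "head") {
  new("BinaryMask", grid = matrix(as.integer(grid), nrow(grid), ncol(grid)),
      classLabel = label)
}

mkEllipse <- function(h, k, a, b, theta) {
  new("EllipseParams", h = h, k = k, a = a, b = b, thetaDeg = theta)
}

# Stem polynomial from ascending coefficients (a0..), zero-padded.
mkStemPoly <- function(coeffs, order, frame, domain) {
  co <- rep(0, 5)
  co[seq_along(coeffs)] <- coeffs
  if (order < 4L) co[(order + 2L):5L] <- 0
  new("StemPolynomial", coeffs = co, order = as.integer(order),
      frame = frame, domain = domain, rss = 0)
}

# Random non-degenerate ellipse.
randomEllipse <- function() {
  a <- runif(1, 60, 240)
  mkEllipse(h = runif(1, -50, 550), k = runif(1, -50, 550),
            a = a, b = a * runif(1, 0.3, 0.9),
            theta = runif(1, -89, 89))
}

# Pure-R BFS flood fill over 8-connectivity: independent oracle for
# largestComponent.
floodLabel <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (grid[r, cc] == 1L && lab[r, cc] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r, cc)); lab[r, cc] <- cur
      while (length(queue)) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (dr in -1:1) for (dc in -1:1) {
          r2 <- p[1L] + dr; c2 <- p[2L] + dc
          if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc &&
              grid[r2, c2] == 1L && lab[r2, c2] == 0L) {
            lab[r2, c2] <- cur
            queue[[length(queue) + 1L]] <- c(r2, c2)
          }
        }
      }
    }
  }
  lab
}

# Dense-sampling sign-change oracle for the stem-ellipse intersection:
# sample the implicit value along the curve, bracket sign changes, refine
# with uniroot, return the root nearest headEnd.
denseIntersectOracle <- function(poly, ellipse, headEnd, nSamples = 1e5,
                                 extend = 0.25) {
  dom <- stemDomain(poly)
  ext <- extend * diff(dom)
  tt <- seq(dom[1] - ext, dom[2] + ext, length.out = nSamples)
  pts <- DiskTilt:::stemPoint(poly, tt)
  q <- ellipseImplicit(ellipse, pts[, 1], pts[, 2])
  sgn <- sign(q)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(idx)) return(NULL)
  f <- function(t) {
    p <- DiskTilt:::stemPoint(poly, t)
    ellipseImplicit(ellipse, p[, 1], p[, 2])
  }
  roots <- vapply(idx, function(i)
    uniroot(f, c(tt[i], tt[i + 1]), tol = 1e-12)$root, numeric(1))
  rp <- DiskTilt:::stemPoint(poly, roots)
  d2 <- (rp[, 1] - headEnd[1])^2 + (rp[, 2] - headEnd[2])^2
  roots[which.min(d2)]
}

# Measurement error over a list of scene params.
sceneErrors <- function(paramsList, config = tiltConfig()) {
  vapply(paramsList, function(p) {
    sc <- generateScene(p)
    angleDeg(measureTilt(sc$head, sc$stem, config)) - trueAngleDeg(p)
  }, numeric(1))
}
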