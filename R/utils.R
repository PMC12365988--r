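# Internal helpers shared across modules.

# Evaluate a polynomial given ascending coefficients c0 + c1 t + ...
polyEval <- function(coeffs, t) {
  out <- rep(0, length(t))
  for (j in rev(seq_along(coeffs))) out <- out * t + coeffs[[j]]
  out
}

# Ascending-coefficient polynomial product.
polyMul <- function(a, b) {
  out <- rep(0, length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[[i]] * b
  }
  out
}

polyAdd <- function(a, b) {
  n <- max(length(a), length(b))
  out <- rep(0, n)
  out[seq_along(a)] <- a
  out[seq_along(b)] <- out[seq_along(b)] + b
  out
}

# Derivative of an ascending-coefficient polynomial.
polyDeriv <- function(coeffs) {
  if (length(coeffs) <= 1L) return(0)
  coeffs[-1L] * seq_len(length(coeffs) - 1L)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

degToRad <- function(d) d * pi / 180
radToDeg <- function(r) r * 180 / pi

# Run expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Structured error with a stable diagnostic code.
diskTiltError <- function(code, msg) {
  stop(structure(
    list(message = sprintf("%s: %s", code, msg), call = sys.call(-1L),
         code = code),
    class = c("DiskTiltError", "error", "condition")))
}

# Length of the longest run of 1s in a 0/1 vector.
longestRun <- function(v) {
  r <- rle(v == 1L)
  if (!any(r$values)) return(0)
  max(r$lengths[r$values])
}

# 8-neighbor binary dilation of a logical matrix.
dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  out[-1L, ] <- out[-1L, ] | m[-nr, ]
  out[-nr, ] <- out[-nr, ] | m[-1L, ]
  out[, -1L] <- out[, -1L] | m[, -nc]
  out[, -nc] <- out[, -nc] | m[, -1L]
  out[-1L, -1L] <- out[-1L, -1L] | m[-nr, -nc]
  out[-1L, -nc] <- out[-1L, -nc] | m[-nr, -1L]
  out[-nr, -1L] <- out[-nr, -1L] | m[-1L, -nc]
  out[-nr, -nc] <- out[-nr, -nc] | m[-1L, -1L]
  out
}

# Chessboard (8-neighbor) distance to the foreground/background interface,
# computed out to maxd steps; pixels further than maxd get Inf.
boundaryDistanceField <- function(grid, maxd) {
  fg <- grid == 1L
  nr <- nrow(grid); nc <- ncol(grid)
  # interface pixels: any pixel whose 8-neighborhood contains both values
  dil <- dilate8(fg)
  ero <- !dilate8(!fg)
  iface <- dil & !ero             # pixels within 1 step of the other class
  d <- matrix(Inf, nr, nc)
  d[iface] <- 1
  frontier <- iface
  k <- 1L
  while (k < maxd && any(frontier)) {
    k <- k + 1L
    nxt <- dilate8(frontier) & !is.finite(d)
    if (!any(nxt)) break
    d[nxt] <- k
    frontier <- nxt
  }
  d
}

# Bilinear image rotation about the grid center, same output size, zero fill.
# Positive angles rotate the image content counter-clockwise as displayed
# (rows down the screen); an exact multiple of 90 degrees on a square grid
# maps pixel centers onto pixel centers, so no interpolation error occurs.
rotateBilinear <- function(img, angleDeg) {
  nr <- nrow(img); nc <- ncol(img)
  th <- degToRad(angleDeg)
  rc <- (nr + 1) / 2; cc <- (nc + 1) / 2
  co <- cos(th); si <- sin(th)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  rows <- matrix(seq_len(nr), nr, nc) - rc
  # inverse mapping; screen y (rows) points down, so CCW display rotation
  # uses the clockwise matrix in (col, row) coordinates
  srcC <- co * cols - si * rows + cc
  srcR <- si * cols + co * rows + rc
  c0 <- floor(srcC); r0 <- floor(srcR)
  fc <- srcC - c0; fr <- srcR - r0
  val <- function(r, c) {
    ok <- r >= 1L & r <= nr & c >= 1L & c <= nc
    out <- matrix(0, nr, nc)
    out[ok] <- img[cbind(r[ok], c[ok])]
    out
  }
  out <- (1 - fr) * (1 - fc) * val(r0, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) +
    fr * fc * val(r0 + 1, c0 + 1)
  out
}
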