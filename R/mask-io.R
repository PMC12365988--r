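# Mask and polygon-label input/output, and conversion to the contour and
# centerline point sets the geometry modules consume.
#
# Coordinate convention (used throughout the package): pixel-centered,
# origin at the top-left, x = column index increasing rightward, y = row
# index increasing downward, both starting at 0. Contours and centerlines
# store (x, y). The final tilt angle is invariant to the y-flip because it
# is an angle between two directions in the same frame.

#' Read a single-channel raster mask
#'
#' Reads a PNG mask and binarizes it with the label rule: any nonzero pixel
#' becomes foreground (1). Masks are class labels, not intensities, so no
#' mid-scale threshold is applied. Multi-channel images are accepted only
#' when all color channels agree (a reducible luminance plane); an alpha
#' channel is ignored.
#'
#' @param path path to a PNG file.
#' @param classLabel \code{"head"} or \code{"stem"}.
#' @return a [BinaryMask-class].
#' @export
readMask <- function(path, classLabel = c("head", "stem")) {
  classLabel <- match.arg(classLabel)
  if (!file.exists(path))
    diskTiltError("MISSING_FILE", sprintf("no such file: %s", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    ch <- min(dim(img)[3L], 3L)
    planes <- lapply(seq_len(ch), function(i) img[, , i])
    if (ch > 1L && !all(vapply(planes[-1L], function(p)
      isTRUE(all.equal(p, planes[[1L]], tolerance = 1e-9)), logical(1L))))
      diskTiltError("MULTI_CHANNEL",
                    "color channels disagree; no reducible luminance plane")
    img <- planes[[1L]]
  }
  grid <- matrix(as.integer(img != 0), nrow(img), ncol(img))
  new("BinaryMask", grid = grid, classLabel = classLabel)
}

#' Write a mask as an 8-bit single-channel PNG
#'
#' Foreground pixels are written as 255, background as 0, so that
#' \code{writeMask(readMask(f))} reproduces a binary input bit-exactly.
#'
#' @param mask a [BinaryMask-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  png::writePNG(mask@grid * 1.0, path)
  invisible(path)
}

#' Parse YOLO segmentation polygon labels
#'
#' Each line holds \code{class_id x1 y1 ... xn yn} with coordinates
#' normalized to [0, 1]; they are denormalized to pixels by multiplying
#' with the image width/height.
#'
#' @param path label file path.
#' @param imageWidth,imageHeight image dimensions in pixels.
#' @return a list of \code{list(classId =, contour =)} entries, one per
#'   line, each contour closed.
#' @export
readYoloPolygons <- function(path, imageWidth, imageHeight) {
  if (!file.exists(path))
    diskTiltError("MISSING_FILE", sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    tok <- suppressWarnings(as.numeric(strsplit(trimws(lines[[i]]), "\\s+")[[1L]]))
    if (anyNA(tok))
      diskTiltError("PARSE_ERROR", sprintf("non-numeric token on line %d", i))
    if (length(tok) < 2L || (length(tok) - 1L) %% 2L != 0L)
      diskTiltError("PARSE_ERROR",
                    sprintf("odd coordinate count on line %d", i))
    coords <- matrix(tok[-1L], ncol = 2L, byrow = TRUE)
    if (nrow(coords) < 3L)
      diskTiltError("PARSE_ERROR",
                    sprintf("polygon on line %d has fewer than 3 vertices", i))
    if (any(coords < 0 | coords > 1))
      diskTiltError("PARSE_ERROR",
                    sprintf("coordinate outside [0, 1] on line %d", i))
    pts <- cbind(x = coords[, 1L] * imageWidth,
                 y = coords[, 2L] * imageHeight)
    list(classId = as.integer(tok[[1L]]),
         contour = new("Contour", points = pts, closed = TRUE))
  })
}

#' Parse a polygon-annotation JSON file
#'
#' Accepts the common annotation layout \code{{"shapes": [{"label": ...,
#' "points": [[x, y], ...]}, ...]}} with pixel coordinates, as a converter
#' into the same representation [readYoloPolygons()] produces.
#'
#' @param path JSON file path.
#' @return a list of \code{list(label =, contour =)} entries.
#' @export
readPolygonJson <- function(path) {
  if (!file.exists(path))
    diskTiltError("MISSING_FILE", sprintf("no such file: %s", path))
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  shapes <- obj$shapes
  if (is.null(shapes)) diskTiltError("PARSE_ERROR", "no \"shapes\" entry")
  lapply(shapes, function(s) {
    pts <- do.call(rbind, lapply(s$points, unlist))
    if (is.null(pts) || nrow(pts) < 3L)
      diskTiltError("PARSE_ERROR", "polygon has fewer than 3 vertices")
    colnames(pts) <- c("x", "y")
    list(label = s$label,
         contour = new("Contour", points = pts, closed = TRUE))
  })
}

#' Rasterize a closed polygon contour to a mask
#'
#' Scanline even-odd fill: a pixel belongs to the polygon when its center
#' (integer coordinates) lies inside.
#'
#' @param contour a closed [Contour-class] in pixel coordinates.
#' @param imageHeight,imageWidth output mask size.
#' @param classLabel mask class.
#' @return a [BinaryMask-class].
#' @export
rasterizeContour <- function(contour, imageHeight, imageWidth,
                             classLabel = c("head", "stem")) {
  classLabel <- match.arg(classLabel)
  p <- contour@points
  grid <- matrix(0L, imageHeight, imageWidth)
  n <- nrow(p)
  xs <- p[, 1L]; ys <- p[, 2L]
  x2 <- xs[c(2:n, 1L)]; y2 <- ys[c(2:n, 1L)]
  for (row in seq_len(imageHeight)) {
    y <- row - 1
    # half-open rule in y avoids double counting at shared vertices
    hit <- (ys <= y & y2 > y) | (y2 <= y & ys > y)
    if (!any(hit)) next
    xi <- xs[hit] + (y - ys[hit]) * (x2[hit] - xs[hit]) / (y2[hit] - ys[hit])
    xi <- sort(xi)
    for (j in seq(1L, length(xi) - 1L, by = 2L)) {
      # round the span ends so vertices stay within 1 px of the raster
      lo <- ceiling(xi[j] - 0.5); hi <- floor(xi[j + 1L] + 0.5 - 1e-9)
      lo <- max(lo, 0L); hi <- min(hi, imageWidth - 1L)
      if (lo <= hi) grid[row, (lo + 1L):(hi + 1L)] <- 1L
    }
  }
  new("BinaryMask", grid = grid, classLabel = classLabel)
}

#' Keep only the largest 8-connected foreground component
#'
#' Robustness step against speckle in model-predicted masks. Ties between
#' equally large components are broken by the topmost-then-leftmost seed
#' pixel. Idempotent.
#'
#' @param mask a nonempty [BinaryMask-class].
#' @return a [BinaryMask-class] with a single component.
#' @export
largestComponent <- function(mask) {
  grid <- mask@grid
  nr <- nrow(grid); nc <- ncol(grid)
  idx <- which(grid == 1L)
  if (!length(idx))
    diskTiltError(paste0("EMPTY_", toupper(mask@classLabel)),
                  "mask has no foreground")
  rank <- integer(nr * nc)
  rank[idx] <- seq_along(idx)
  rc <- arrayInd(idx, c(nr, nc))
  r <- rc[, 1L]; cl <- rc[, 2L]
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1L]; c2 <- cl + off[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- integer(length(idx))
    nb[ok] <- rank[(c2[ok] - 1L) * nr + r2[ok]]
    keep <- ok & nb > 0L
    if (any(keep)) edges <- c(edges, rbind(seq_along(idx)[keep], nb[keep]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  big <- max(comp$csize)
  cand <- which(comp$csize == big)
  if (length(cand) > 1L) {
    # topmost-then-leftmost seed: minimal (row, col) in row-major scan order
    key <- (r - 1L) * nc + (cl - 1L)
    seedKey <- vapply(cand, function(k) min(key[comp$membership == k]),
                      numeric(1L))
    cand <- cand[which.min(seedKey)]
  }
  out <- matrix(0L, nr, nc)
  out[idx[comp$membership == cand[1L]]] <- 1L
  new("BinaryMask", grid = out, classLabel = mask@classLabel)
}

# Clockwise 8-neighbor offsets (x right, y down), starting west:
# W, NW, N, NE, E, SE, S, SW
.mooreOffsets <- cbind(dx = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
                       dy = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L))

#' Trace the outer boundary of a mask
#'
#' Moore-neighbor tracing with 8-connectivity, clockwise orientation,
#' starting from the topmost-then-leftmost foreground pixel. The largest
#' component is taken first. Every returned pixel is foreground with at
#' least one background 4-neighbor or lies on the image border.
#'
#' @param mask a nonempty [BinaryMask-class].
#' @return a closed [Contour-class] of pixel coordinates.
#' @export
extractOuterContour <- function(mask) {
  mask <- largestComponent(mask)
  grid <- mask@grid
  nr <- nrow(grid); nc <- ncol(grid)
  fg <- function(x, y) x >= 0L && x < nc && y >= 0L && y < nr &&
    grid[y + 1L, x + 1L] == 1L
  # topmost-then-leftmost foreground pixel
  idx <- which(t(grid) == 1L)[1L]          # row-major scan
  sy <- (idx - 1L) %/% nc; sx <- (idx - 1L) %% nc
  if (sum(grid) == 1L)
    return(new("Contour", points = cbind(x = sx, y = sy), closed = TRUE))
  pts <- matrix(NA_real_, 8L * sum(grid) + 8L, 2L)
  pts[1L, ] <- c(sx, sy)
  np <- 1L
  cx <- sx; cy <- sy
  backtrack <- 1L                          # entered from the west
  # termination: stop when a (pixel, entry-direction) state repeats — the
  # trace is then provably periodic. A ragged boundary can legitimately
  # pass through the start pixel more than once, so first-return-to-start
  # would truncate it.
  seen <- new.env(hash = TRUE, parent = emptyenv())
  maxIter <- 8L * sum(grid) + 8L
  for (iter in seq_len(maxIter)) {
    found <- FALSE
    for (step in seq_len(8L)) {
      j <- ((backtrack - 1L + step - 1L) %% 8L) + 1L
      nx <- cx + .mooreOffsets[j, 1L]; ny <- cy + .mooreOffsets[j, 2L]
      if (fg(nx, ny)) {
        # next backtrack: direction of the previously checked (background)
        # neighbor, as seen from the new pixel
        prev <- ((j - 2L) %% 8L) + 1L
        bx <- cx + .mooreOffsets[prev, 1L]; by <- cy + .mooreOffsets[prev, 2L]
        backtrack <- which(.mooreOffsets[, 1L] == bx - nx &
                             .mooreOffsets[, 2L] == by - ny)
        cx <- nx; cy <- ny
        found <- TRUE
        break
      }
    }
    if (!found) break                      # isolated pixel (cannot happen here)
    key <- sprintf("%d_%d_%d", cx, cy, backtrack)
    if (!is.null(seen[[key]])) break
    seen[[key]] <- TRUE
    if (cx == sx && cy == sy) next         # start already recorded
    np <- np + 1L
    pts[np, ] <- c(cx, cy)
  }
  out <- unique(pts[seq_len(np), , drop = FALSE])
  colnames(out) <- c("x", "y")
  new("Contour", points = out, closed = TRUE)
}

#' Extract the stem centerline as per-scanline midpoints
#'
#' Scans along the dominant-extent axis of the mask (the coordinate with
#' the larger bounding-box extent; ties scan along y). Each scanline
#' contributes the midpoint of its longest foreground run; scanlines with
#' no foreground are dropped. Multi-run scanlines (a stem split by noise)
#' keep the longest run only.
#'
#' @param mask a nonempty stem [BinaryMask-class].
#' @return a [Centerline-class] with at least 4 points.
#' @export
extractCenterline <- function(mask) {
  grid <- mask@grid
  if (!any(grid == 1L))
    diskTiltError(paste0("EMPTY_", toupper(mask@classLabel)),
                  "mask has no foreground")
  rows <- which(rowSums(grid) > 0); cols <- which(colSums(grid) > 0)
  extY <- diff(range(rows)); extX <- diff(range(cols))
  axis <- if (extY >= extX) "y-major" else "x-major"
  scanMid <- function(v) {
    r <- rle(v == 1L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    fgRuns <- which(r$values)
    best <- fgRuns[which.max(r$lengths[fgRuns])]
    # pixel coords are 0-based: midpoint of [start-1, end-1]
    (starts[best] + ends[best]) / 2 - 1
  }
  if (axis == "y-major") {
    mids <- vapply(rows, function(rr) scanMid(grid[rr, ]), numeric(1L))
    pts <- cbind(x = mids, y = rows - 1)
  } else {
    mids <- vapply(cols, function(cc) scanMid(grid[, cc]), numeric(1L))
    pts <- cbind(x = cols - 1, y = mids)
  }
  if (nrow(pts) < 4L)
    diskTiltError("CENTERLINE_TOO_SHORT",
                  sprintf("only %d usable scanlines (need >= 4)", nrow(pts)))
  new("Centerline", points = pts, axis = axis)
}
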