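# Rasterization and contour extraction. Masks are scanline-filled (a pixel is
# foreground iff its centre lies inside the polygon); contours are recovered
# at the 0.5 iso-level of the binary raster (marching squares), which gives a
# subpixel boundary and roughly halves rasterization bias relative to
# pixel-boundary polygons.

#' Rasterize a contour into a binary mask
#'
#' Scanline fill: a pixel belongs to the foreground when its centre lies
#' inside the polygon. The mask area times the squared scale converges to the
#' polygon area as the scale decreases.
#'
#' @param contour a [SporeContour-class] or two-column vertex matrix (µm).
#' @param scaleUmPerPx µm per pixel (> 0).
#' @return A [SporeMask-class].
#' @examples
#' sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' maskArea(rasterize(sq, 0.1))  # ~100 um^2
#' @export
rasterize <- function(contour, scaleUmPerPx) {
  v <- asVertices(contour)
  s <- scaleUmPerPx
  if (!isScalarFinite(s) || s <= 0) stop("scaleUmPerPx must be positive")
  offset <- c(min(v[, 1]), min(v[, 2])) - 1.5 * s
  nx <- ceiling((max(v[, 1]) - offset[1]) / s + 1.5)
  ny <- ceiling((max(v[, 2]) - offset[2]) / s + 1.5)
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  x1 <- v[, 1]; y1 <- v[, 2]; x2 <- x1[nxt]; y2 <- y1[nxt]
  pix <- matrix(0, ny, nx)
  ys <- offset[2] + (seq_len(ny) - 0.5) * s
  for (i in seq_len(ny)) {
    yy <- ys[i]
    cr <- which((y1 <= yy & y2 > yy) | (y2 <= yy & y1 > yy))
    if (length(cr) < 2L) next
    xc <- sort(x1[cr] + (yy - y1[cr]) * (x2[cr] - x1[cr]) / (y2[cr] - y1[cr]))
    for (k in seq(1L, length(xc) - 1L, by = 2L)) {
      j1 <- floor((xc[k] - offset[1]) / s + 0.5) + 1L
      j2 <- ceiling((xc[k + 1L] - offset[1]) / s + 0.5) - 1L
      if (j2 >= j1) pix[i, j1:j2] <- 1
    }
  }
  if (sum(pix) < 50)
    stop("scale too coarse: fewer than 50 foreground pixels")
  SporeMask(pix, s, offset)
}

#' Extract a subpixel contour from a binary mask
#'
#' Recovers the closed boundary at the 0.5 iso-level of the binary raster
#' (marching squares on the zero-padded pixel grid) in µm coordinates. The
#' polygon area is within O(scale) of the pixel-count area. Masks whose
#' silhouette encloses less than the area of 50 pixels (degenerate,
#' e.g. one-pixel-wide blobs) are rejected.
#'
#' @param mask a [SporeMask-class].
#' @return A [SporeContour-class] (counterclockwise, µm coordinates).
#' @export
extractContour <- function(mask) {
  stopifnot(is(mask, "SporeMask"))
  p <- mask@pixels
  s <- mask@scaleUmPerPx
  z <- matrix(0, nrow(p) + 2L, ncol(p) + 2L)
  z[2:(nrow(p) + 1L), 2:(ncol(p) + 1L)] <- p
  xs <- mask@offset[1] + (seq_len(ncol(z)) - 1.5) * s
  ys <- mask@offset[2] + (seq_len(nrow(z)) - 1.5) * s
  eroded <- EBImage::erode(p, EBImage::makeBrush(3, "box"))
  if (sum(eroded) == 0)
    stop("degenerate mask: no interior pixels (one-pixel-wide blob)")
  iso <- isoband::isolines(xs, ys, z, levels = 0.5)[[1]]
  ids <- unique(iso$id)
  if (length(ids) != 1L)
    stop("mask boundary split into ", length(ids),
         " components; expected a single closed contour")
  v <- cbind(iso$x, iso$y)
  ctr <- SporeContour(v, checkSimple = FALSE)
  if (polygonArea(ctr) < 50 * s^2)
    stop("degenerate mask: enclosed area below the 50-pixel minimum")
  ctr
}

#' Segment the largest object of a grayscale image into a spore mask
#'
#' Thresholds a grayscale raster (Otsu by default, or a fixed threshold),
#' auto-detects polarity by border sampling (the object is taken as the side
#' of the threshold away from the border intensity), keeps the largest
#' connected component, and fills interior holes. Binary input passes
#' through unchanged up to those clean-up steps.
#'
#' @param image numeric matrix (rows = y, columns = x), any intensity range.
#' @param scaleUmPerPx µm per pixel.
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param threshold fixed threshold (required for \code{method = "fixed"}).
#' @param offset µm coordinates of the lower-left raster corner.
#' @return A [SporeMask-class].
#' @export
segmentImage <- function(image, scaleUmPerPx, method = c("otsu", "fixed"),
                         threshold = NULL, offset = c(0, 0)) {
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0L)
    stop("image must be a non-empty numeric matrix")
  if (!isScalarFinite(scaleUmPerPx) || scaleUmPerPx <= 0)
    stop("scaleUmPerPx must be positive")
  rng <- range(image)
  if (method == "otsu") {
    if (rng[1] == rng[2]) stop("no foreground: image is constant")
    norm <- (image - rng[1]) / (rng[2] - rng[1])
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    thr <- rng[1] + thr * (rng[2] - rng[1])
  } else {
    if (!isScalarFinite(threshold)) stop("method 'fixed' needs a threshold")
    thr <- threshold
  }
  border <- c(image[1, ], image[nrow(image), ], image[, 1], image[, ncol(image)])
  brightObject <- mean(border) <= thr
  fg <- if (brightObject) image > thr else image < thr
  if (!any(fg)) stop("no foreground after thresholding")
  lab <- EBImage::bwlabel(fg * 1)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  comparable <- sum(sizes > 0.5 * sizes[big]) - 1L
  if (comparable > 0L)
    warning(comparable, " additional component(s) above 50% of the largest ",
            "(sizes: ", paste(sort(sizes, decreasing = TRUE), collapse = ", "),
            ")")
  pix <- EBImage::fillHull((lab == big) * 1)
  SporeMask(as.matrix(pix), scaleUmPerPx, offset)
}
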