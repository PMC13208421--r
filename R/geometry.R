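# Planar polygon primitives for silhouette morphometry. All polygons are
# two-column (x, y) matrices in µm, stored open (implicit closing edge).

isScalarFinite <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Accept a SporeContour or a bare vertex matrix.
asVertices <- function(x) {
  if (is(x, "SporeContour")) return(x@vertices)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || ncol(x) != 2L || !is.numeric(x))
    stop("expected a SporeContour or a two-column numeric vertex matrix")
  x
}

# Drop a repeated closing vertex and consecutive duplicates; force
# counterclockwise orientation.
normalizeVertices <- function(v) {
  v <- asVertices(v)
  n <- nrow(v)
  if (n >= 2L && all(abs(v[n, ] - v[1, ]) < 1e-300)) v <- v[-n, , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(v))) > 0)
  v <- v[keep, , drop = FALSE]
  if (nrow(v) < 3L) stop("polygon needs at least three distinct vertices")
  if (polygonSignedArea(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  dimnames(v) <- NULL
  v
}

polygonSignedArea <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

#' Polygon area by the shoelace formula
#'
#' @param x a [SporeContour-class] or a two-column vertex matrix.
#' @return The absolute enclosed area (µm² for contours in µm).
#' @examples
#' polygonArea(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))  # 100
#' @export
polygonArea <- function(x) abs(polygonSignedArea(asVertices(x)))

#' Convex hull of a polygon
#'
#' Standard planar convex hull of the vertex set, returned counterclockwise.
#'
#' @param x a [SporeContour-class] or a two-column vertex matrix.
#' @return Two-column matrix of hull vertices, counterclockwise.
#' @export
convexHullOf <- function(x) {
  v <- asVertices(x)
  h <- v[grDevices::chull(v[, 1], v[, 2]), , drop = FALSE]
  if (nrow(h) >= 3L && polygonSignedArea(h) < 0)
    h <- h[rev(seq_len(nrow(h))), , drop = FALSE]
  dimnames(h) <- NULL
  h
}

cross2 <- function(o, a, b) {
  (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
}

segmentsCross <- function(p1, p2, q1, q2, eps) {
  d1 <- cross2(p1, p2, q1); d2 <- cross2(p1, p2, q2)
  d3 <- cross2(q1, q2, p1); d4 <- cross2(q1, q2, p2)
  if (((d1 > eps & d2 < -eps) | (d1 < -eps & d2 > eps)) &&
      ((d3 > eps & d4 < -eps) | (d3 < -eps & d4 > eps))) return(TRUE)
  onSeg <- function(a, b, c) {
    c[1] >= min(a[1], b[1]) - eps && c[1] <= max(a[1], b[1]) + eps &&
    c[2] >= min(a[2], b[2]) - eps && c[2] <= max(a[2], b[2]) + eps
  }
  if (abs(d1) <= eps && onSeg(p1, p2, q1)) return(TRUE)
  if (abs(d2) <= eps && onSeg(p1, p2, q2)) return(TRUE)
  if (abs(d3) <= eps && onSeg(q1, q2, p1)) return(TRUE)
  if (abs(d4) <= eps && onSeg(q1, q2, p2)) return(TRUE)
  FALSE
}

#' Test whether a closed polygon is simple
#'
#' Checks that no two non-adjacent edges intersect, using a bounding-box
#' sweep over edges sorted by their minimum x, which is near-linear for the
#' short-edged contours this package produces.
#'
#' @param x a [SporeContour-class] or a two-column vertex matrix.
#' @return \code{TRUE} if the polygon has no self-intersection.
#' @export
isSimplePolygon <- function(x) {
  v <- asVertices(x)
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  nxt <- c(2:n, 1L)
  eps <- 1e-12 * max(abs(v), 1)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- x1[nxt]; y2 <- y1[nxt]
  xmin <- pmin(x1, x2); xmax <- pmax(x1, x2)
  ymin <- pmin(y1, y2); ymax <- pmax(y1, y2)
  ord <- order(xmin)
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    for (b in (a + 1L):n) {
      j <- ord[b]
      if (xmin[j] > xmax[i] + eps) break
      d <- abs(i - j)
      if (d == 1L || d == n - 1L) next  # adjacent edges share a vertex
      if (ymin[i] > ymax[j] + eps || ymin[j] > ymax[i] + eps) next
      if (segmentsCross(c(x1[i], y1[i]), c(x2[i], y2[i]),
                        c(x1[j], y1[j]), c(x2[j], y2[j]), eps))
        return(FALSE)
    }
  }
  TRUE
}

#' Suprahilar-depression percentage of a silhouette
#'
#' The convex-hull concavity statistic: the silhouette area is subtracted
#' from the area of its convex hull and the difference is expressed as the
#' percentage of the hull area occupied by concavity,
#' \deqn{100 \, (A_{hull} - A) / A_{hull}.}
#' Both areas are computed by the shoelace formula; the hull is the standard
#' planar convex hull of the vertices. Differences below the floating-point
#' resolution of the shoelace sums (1e-12 of the hull area) are snapped to
#' exactly zero, so convex polygons measure 0.
#'
#' @param x a [SporeContour-class] or a two-column vertex matrix.
#' @param check verify that a bare vertex matrix is a simple polygon
#'   (self-intersecting input is an error). Contours carried by a
#'   [SporeContour-class] were verified at construction and skip the check.
#' @return Depression percentage in \code{[0, 100)}.
#' @examples
#' sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' suprahilarDepression(sq)  # 0: convex
#' @export
suprahilarDepression <- function(x, check = !is(x, "SporeContour")) {
  v <- asVertices(x)
  if (check) {
    v <- normalizeVertices(v)
    if (!isSimplePolygon(v)) stop("polygon is self-intersecting")
  }
  a <- polygonArea(v)
  if (a <= 0) stop("polygon has no area")
  ha <- polygonArea(convexHullOf(v))
  ha <- max(ha, a)
  if (ha - a <= 1e-12 * ha) return(0)
  100 * (ha - a) / ha
}

#' Feret length, perpendicular width and orientation of a silhouette
#'
#' The length is the maximum caliper (Feret) diameter, found by an all-pairs
#' search over the convex-hull vertices; the width is the maximum extent of
#' the hull perpendicular to the length axis.
#'
#' @param x a [SporeContour-class] or a two-column vertex matrix.
#' @return A list with elements \code{L}, \code{W} (µm) and
#'   \code{orientationDeg} (long-axis orientation, degrees in \code{[0, 180)}).
#' @examples
#' # Feret length of a rectangle is its diagonal
#' measureAxes(cbind(c(0, 12, 12, 0), c(0, 0, 5, 5)))$L  # 13
#' @export
measureAxes <- function(x) {
  h <- convexHullOf(x)
  if (nrow(h) < 3L) stop("degenerate (collinear) polygon")
  d <- as.matrix(stats::dist(h))
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  L <- d[ij[1], ij[2]]
  if (L <= 0) stop("degenerate polygon")
  u <- (h[ij[2], ] - h[ij[1], ]) / L
  perp <- c(-u[2], u[1])
  proj <- h %*% perp
  W <- max(proj) - min(proj)
  ang <- atan2(u[2], u[1]) * 180 / pi
  ang <- ang %% 180
  list(L = L, W = W, orientationDeg = ang)
}

#' Measure the geometric primitives of one silhouette
#'
#' Computes the convex hull, shape and hull areas, the suprahilar-depression
#' percentage, and the Feret length/width on one contour.
#'
#' @param contour a [SporeContour-class] or a two-column vertex matrix
#'   (a bare matrix is first validated and normalised).
#' @return A [GeometryResult-class].
#' @export
measureContour <- function(contour) {
  if (!is(contour, "SporeContour"))
    contour <- SporeContour(asVertices(contour), checkSimple = TRUE)
  v <- contour@vertices
  hull <- convexHullOf(v)
  a <- polygonArea(v)
  ha <- max(polygonArea(hull), a)
  dep <- if (ha - a <= 1e-12 * ha) 0 else 100 * (ha - a) / ha
  ax <- measureAxes(v)
  new("GeometryResult", contour = contour, hull = hull,
      shapeAreaUm2 = a, hullAreaUm2 = ha, depressionPct = dep,
      LUm = ax$L, WUm = ax$W, orientationDeg = ax$orientationDeg)
}

# Distance from each point of `pts` to the closed polyline `poly`
# (point-to-segment, not vertex-to-vertex).
pointsToPolylineDist <- function(pts, poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  p1x <- poly[, 1]; p1y <- poly[, 2]
  dx <- poly[nxt, 1] - p1x; dy <- poly[nxt, 2] - p1y
  len2 <- pmax(dx^2 + dy^2, 1e-300)
  vapply(seq_len(nrow(pts)), function(i) {
    ax <- pts[i, 1]; ay <- pts[i, 2]
    t <- pmin(pmax(((ax - p1x) * dx + (ay - p1y) * dy) / len2, 0), 1)
    sqrt(min((ax - (p1x + t * dx))^2 + (ay - (p1y + t * dy))^2))
  }, numeric(1))
}

# Symmetric Hausdorff distance between two closed contours (used by the
# round-trip accuracy checks).
hausdorffDistance <- function(a, b) {
  a <- asVertices(a); b <- asVertices(b)
  max(pointsToPolylineDist(a, b), pointsToPolylineDist(b, a))
}
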