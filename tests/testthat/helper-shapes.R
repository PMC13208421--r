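# Shape fixtures and independent oracles used across the suite. All fixtures
# are built in code; the oracles deliberately avoid the package's internal
# helpers where they can (shoelace re-implemented, pixel-count depression).

unitSquare <- function(side = 10) {
  cbind(c(0, side, side, 0), c(0, 0, side, side))
}

# 10 x 10 square with an inward triangular notch of area `notchArea` whose
# base lies on the bottom edge (hull = the square).
notchedSquare <- function(side = 10, notchArea = 5) {
  h <- notchArea  # triangle base 2: area = 2 * h / 2 = h
  rbind(c(0, 0), c(4, 0), c(5, h), c(6, 0), c(side, 0),
        c(side, side), c(0, side))
}

ellipseContour <- function(L = 12, W = 5, n = 256) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(L / 2 * cos(t), W / 2 * sin(t))
}

rotatePoly <- function(v, angleDeg, center = c(0, 0)) {
  th <- angleDeg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  sweep(sweep(v, 2, center) %*% t(R), 2, center, "+")
}

# Independent shoelace (written from the textbook formula, not the package).
oracleArea <- function(v) {
  n <- nrow(v)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2]
  }
  abs(s) / 2
}

oracleDepression <- function(v) {
  hull <- v[grDevices::chull(v), , drop = FALSE]
  100 * (oracleArea(hull) - oracleArea(v)) / oracleArea(hull)
}

# Brute-force raster oracle: fill the contour and its convex hull on the
# same fine grid and take the depression from pixel counts.
pixelDepression <- function(v, scale = 0.005) {
  shape <- sum(maskPixels(rasterize(v, scale)))
  hull <- sum(maskPixels(rasterize(convexHullOf(v), scale)))
  100 * (hull - shape) / hull
}
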