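test_that("convex silhouettes have zero depression, exactly", {
  shapes <- list(unitSquare(),
                 ellipseContour(12, 5),
                 ellipseContour(7, 7, n = 128),
                 rotatePoly(unitSquare(3), 31))
  for (v in shapes) expect_identical(suprahilarDepression(v), 0)
})

test_that("notched square gives the analytic depression", {
  v <- notchedSquare(10, 5)
  # hull is the 10 x 10 square (area 100), notch removes area 5
  expect_equal(suprahilarDepression(v), 5, tolerance = 1e-12)
  expect_equal(oracleDepression(v), 5, tolerance = 1e-12)
  expect_equal(polygonArea(v), 95)
  expect_equal(polygonArea(convexHullOf(v)), 100)
})

test_that("depression is invariant under rigid motion and scaling", {
  v <- notchedSquare(10, 3)
  ref <- suprahilarDepression(v)
  for (ang in c(17, 90, 133.7, 258)) {
    rot <- rotatePoly(v, ang, center = c(3, -2))
    expect_equal(suprahilarDepression(rot), ref, tolerance = 1e-9)
  }
  expect_equal(suprahilarDepression(v * 37.2), ref, tolerance = 1e-9)
  expect_equal(suprahilarDepression(sweep(v, 2, c(-120, 55), "+")), ref,
               tolerance = 1e-9)
})

test_that("polygon depression agrees with the pixel-count oracle", {
  p <- sporeShapeParams("ellipsoid", 12, 5, targetConcavity = 0.04)
  v <- vertices(generateContour(p))
  expect_lt(abs(suprahilarDepression(v) - pixelDepression(v, 0.005)), 0.1)
  v2 <- notchedSquare(10, 5)
  expect_lt(abs(5 - pixelDepression(v2, 0.005)), 0.1)
})

test_that("hull area dominates shape area; equality only at zero depression", {
  withr::with_seed(42, {
    for (i in 1:20) {
      # star-shaped polygon with random radial jitter (simple by construction)
      t <- seq(0, 2 * pi, length.out = 81)[-81]
      r <- 5 + runif(80, -1.5, 1.5)
      v <- cbind(r * cos(t), r * sin(t))
      a <- polygonArea(v)
      ha <- polygonArea(convexHullOf(v))
      expect_gte(ha, a)
      dep <- suprahilarDepression(v)
      expect_identical(dep == 0, ha - a <= 1e-12 * ha)
    }
  })
})

test_that("deepening the notch strictly increases depression", {
  p <- sporeShapeParams("ellipsoid", 12, 5)
  base <- SporeHull:::baseOvoid(p, 256)
  deps <- vapply(c(0.2, 0.5, 0.9, 1.4, 1.9), function(d)
    suprahilarDepression(SporeHull:::applyNotch(base, d, p), check = FALSE),
    numeric(1))
  expect_true(all(diff(deps) > 0))
})

test_that("Feret axes match analytic values", {
  rect <- cbind(c(0, 12, 12, 0), c(0, 0, 5, 5))
  ax <- measureAxes(rect)
  # regression pin: the Feret length of a rectangle is its diagonal
  expect_equal(ax$L, 13, tolerance = 1e-12)
  expect_lte(ax$W, 12)
  expect_equal(ax$W, 120 / 13, tolerance = 1e-12)

  circ <- measureAxes(ellipseContour(10, 10, n = 256))
  expect_equal(circ$L, 10, tolerance = 0.01)
  expect_equal(circ$W, 10, tolerance = 0.01)

  ell <- measureAxes(rotatePoly(ellipseContour(12, 5), 40))
  expect_equal(ell$L, 12, tolerance = 0.001)
  expect_equal(ell$W, 5, tolerance = 0.001)
  expect_equal(ell$orientationDeg, 40, tolerance = 1)
})

test_that("degenerate and self-intersecting polygons are rejected", {
  bowtie <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_false(isSimplePolygon(bowtie))
  expect_error(suprahilarDepression(bowtie), "self-intersecting")
  collinear <- cbind(0:4, 2 * (0:4))
  expect_error(measureAxes(collinear), "degenerate|three distinct")
})

test_that("measureContour bundles consistent primitives", {
  ct <- sporeContourFixture("pulverulentus")
  g <- measureContour(ct)
  expect_s4_class(g, "GeometryResult")
  expect_equal(depressionPct(g), suprahilarDepression(ct), tolerance = 1e-12)
  expect_gte(hullArea(g), shapeArea(g))
  expect_gte(sporeLength(g), sporeWidth(g))
  expect_equal(shapeArea(g), polygonArea(ct), tolerance = 1e-12)
})
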