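test_that("zero-target ellipsoid contour is convex", {
  p <- sporeShapeParams("ellipsoid", 12, 5, targetConcavity = 0)
  ct <- generateContour(p)
  expect_identical(suprahilarDepression(ct), 0)
})

test_that("generated concavity hits the target within calibration tolerance", {
  # oracle: hull and polygon areas recomputed by an independent shoelace
  p <- sporeShapeParams("ellipsoid", 12, 5, targetConcavity = 0.04)
  v <- vertices(generateContour(p))
  expect_equal(oracleDepression(v), 4.0, tolerance = 0.05 / 4.0)

  for (target in c(0.005, 0.02, 0.05, 0.08)) {
    pj <- sporeShapeParams("subamygdaliform", 12.7, 5.3,
                           targetConcavity = target)
    dep <- suprahilarDepression(generateContour(pj)) / 100
    expect_lt(abs(dep - target), 5e-4)
  }
})

test_that("amygdaliform preset reaches the pronounced-depression regime", {
  ct <- sporeContourFixture("pulverulentus")
  expect_gt(suprahilarDepression(ct), 3)
  expect_lt(suprahilarDepression(sporeContourFixture("mediterraneensis")),
            2.5)
})

test_that("generated axes are calibrated to the nominal dimensions", {
  for (fam in c("ellipsoid", "subamygdaliform", "amygdaliform")) {
    p <- sporeShapeParams(fam, 12.3, 4.9, targetConcavity = 0.03,
                          apexSharpness = 0.7, apiculusOffset = 0.3)
    ax <- measureAxes(generateContour(p))
    expect_equal(ax$L, 12.3, tolerance = 0.01)
    expect_equal(ax$W, 4.9, tolerance = 0.01)
  }
})

test_that("contour generation is deterministic and infeasibility is explicit", {
  p <- sporeShapeParams("ellipsoid", 12, 5, targetConcavity = 0.05)
  expect_identical(vertices(generateContour(p)),
                   vertices(generateContour(p)))
  # narrow notch cannot carve 20% of the hull
  bad <- sporeShapeParams("ellipsoid", 12, 5, targetConcavity = 0.2,
                          notchWidthFrac = 0.1)
  err <- tryCatch(generateContour(bad), condition = identity)
  expect_s3_class(err, "sporeHullInfeasibleConcavity")
  expect_true(is.numeric(err$attainable) && err$attainable < 0.2)
  expect_match(conditionMessage(err), "attainable maximum")
  # apiculus alone contributes concavity: near-zero targets are infeasible
  lowErr <- tryCatch(
    generateContour(sporeShapeParams("amygdaliform", 12.29, 4.87,
                                     apiculusOffset = 0.3,
                                     targetConcavity = 0.0005)),
    condition = identity)
  expect_s3_class(lowErr, "sporeHullInfeasibleConcavity")
})

test_that("rasterization recovers known areas", {
  m <- rasterize(unitSquare(10), 0.1)
  expect_equal(maskArea(m), 100, tolerance = 0.02)
  m2 <- rasterize(ellipseContour(12, 5), 0.02)
  expect_equal(maskArea(m2), pi * 12 * 5 / 4, tolerance = 0.01)
  expect_error(rasterize(unitSquare(1), 0.5), "fewer than 50")
})

test_that("mask-derived depression of a convex contour stays below 0.5%", {
  m <- rasterize(ellipseContour(12, 5), 0.02)
  dep <- depressionPct(measureContour(extractContour(m)))
  expect_lte(dep, 0.5)
})

test_that("halving the raster scale at least halves the area error", {
  v <- ellipseContour(11, 4.6, n = 512)
  trueA <- polygonArea(v)
  errAt <- function(s) abs(maskArea(rasterize(v, s)) - trueA)
  # quartering the pixel size: errors are O(scale) with fluctuation, so
  # compare across a 4x scale ratio
  expect_lt(errAt(0.02), 0.5 * errAt(0.08))
})

test_that("population sampling is reproducible and respects the hierarchy", {
  cfg <- speciesPreset("mediterraneensis", pCollections = 4,
                       mBasidiomes = 3, nPerBasidiome = 2, seed = 11)
  pop <- samplePopulation(cfg)
  expect_identical(pop, samplePopulation(cfg))
  expect_equal(nrow(pop), 4 * 3 * 2)
  expect_equal(length(unique(pop$collection_id)), 4)
  expect_equal(length(unique(pop$basidiome_id)), 12)
  expect_true(all(pop$length_um > pop$width_um))
  expect_true(all(pop$concavity > 0 & pop$concavity <= 0.08))
})

test_that("degenerate SDs give identical spores", {
  cfg <- populationConfig("degenerate", meanL = 12, sdLBetween = 0,
                          meanW = 5, sdWBetween = 0, withinSdFactor = 0,
                          concavityLogMean = log(0.02), concavityLogSd = 0,
                          pCollections = 2L, mBasidiomes = 2L,
                          nPerBasidiome = 2L, seed = 3L)
  pop <- samplePopulation(cfg)
  expect_true(all(pop$length_um == 12))
  expect_true(all(pop$width_um == 5))
  expect_true(all(pop$concavity == 0.02))
})

test_that("excessive truncation is reported", {
  cfg <- populationConfig("noisy", meanL = 6, sdLBetween = 3, meanW = 5,
                          sdWBetween = 3, corrLW = 0, pCollections = 10L,
                          mBasidiomes = 2L, nPerBasidiome = 5L, seed = 5L)
  expect_warning(samplePopulation(cfg), "truncation")
})

test_that("sampled collection means recover the configured parameters", {
  cfg <- speciesPreset("mediterraneensis", pCollections = 17,
                       mBasidiomes = 10, nPerBasidiome = 5, seed = 21)
  pop <- samplePopulation(cfg)
  collL <- tapply(pop$length_um, pop$collection_id, mean)
  sem <- sd(collL) / sqrt(length(collL))
  expect_lt(abs(mean(collL) - 12.67), 3 * sem)
  collW <- tapply(pop$width_um, pop$collection_id, mean)
  expect_lt(abs(mean(collW) - 5.33), 3 * sd(collW) / sqrt(length(collW)))
})
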