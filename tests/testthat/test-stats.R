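test_that("exact Mann-Whitney matches independent references", {
  r <- compareGroups(c(1, 2, 3), c(4, 5, 6), method = "mw")
  expect_equal(testStatistic(r), 0)
  expect_equal(pValue(r), 2 / 20)  # 2 of the C(6,3) = 20 rank assignments

  # dual route: the enumeration must agree with the classical exact test
  # on tie-free samples for every size pair up to 8
  withr::with_seed(99, {
    for (n1 in c(3, 5, 8)) {
      for (n2 in c(3, 6, 8)) {
        a <- rnorm(n1); b <- rnorm(n2, 0.5)
        ours <- compareGroups(a, b, method = "mw")
        ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
        expect_equal(pValue(ours), ref$p.value, tolerance = 1e-12)
        expect_equal(testStatistic(ours), unname(ref$statistic))
      }
    }
  })
})

test_that("degenerate group comparisons behave as documented", {
  expect_equal(pValue(compareGroups(rep(2, 4), rep(2, 4), method = "mw")), 1)
  r <- compareGroups(c(1, 2, 3, 4), c(1, 2, 3, 4), method = "t")
  expect_equal(testStatistic(r), 0)
  expect_equal(pValue(r), 1)
  expect_error(compareGroups(1, c(1, 2)), "at least 2")
})

test_that("auto mode routes by Shapiro-Wilk normality", {
  withr::with_seed(1, {
    gaussA <- rnorm(30); gaussB <- rnorm(30, 1)
    heavy <- rexp(30)
  })
  rt <- compareGroups(gaussA, gaussB)
  expect_equal(rt@method, "welch_t")
  rm <- compareGroups(gaussA, heavy)
  expect_equal(rm@method, "mann_whitney")
  expect_true(any(rm@details$shapiroP <= 0.05))
})

test_that("large-sample Mann-Whitney approximation tracks the reference", {
  withr::with_seed(4, {
    a <- rnorm(25); b <- rnorm(30, 0.8)
  })
  ours <- compareGroups(a, b, method = "mw")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(pValue(ours), ref$p.value, tolerance = 1e-9)
})

test_that("star assignment is a pure threshold function", {
  withr::with_seed(8, ps <- c(runif(50), 0.05, 0.01, 0.001, 0, 1))
  for (p in ps) {
    expected <- if (p < 0.001) "***" else if (p < 0.01) "**" else
      if (p < 0.05) "*" else "ns"
    expect_identical(SporeHull:::assignStars(p), expected)
  }
})

test_that("preset populations separate as the published comparisons do", {
  pulv <- samplePopulation(speciesPreset("pulverulentus", pCollections = 15,
                                         mBasidiomes = 5, nPerBasidiome = 4,
                                         seed = 2))
  medi <- samplePopulation(speciesPreset("mediterraneensis",
                                         pCollections = 17, mBasidiomes = 5,
                                         nPerBasidiome = 4, seed = 3))
  wP <- tapply(pulv$width_um, pulv$collection_id, mean)
  wM <- tapply(medi$width_um, medi$collection_id, mean)
  r <- compareGroups(wP, wM, method = "t")
  expect_lt(pValue(r), 0.01)          # widths separate strongly
  expect_lt(mean(wP), mean(wM))       # in the published direction
})

test_that("isoprobability ellipse has the chi-square geometry", {
  withr::with_seed(10, {
    pts <- MASS::mvrnorm(500, c(3, 7), diag(2), empirical = TRUE)
  })
  e <- isoEllipse(pts, 0.95)
  expect_equal(e@semiMajor, sqrt(qchisq(0.95, 2)), tolerance = 1e-9)
  expect_equal(e@semiMinor, sqrt(qchisq(0.95, 2)), tolerance = 1e-9)
  expect_equal(e@center, c(3, 7), tolerance = 1e-9)

  e2 <- isoEllipse(pts * 2, 0.95)
  expect_equal(e2@semiMajor, 2 * e@semiMajor, tolerance = 1e-9)
  expect_equal(e2@semiMinor, 2 * e@semiMinor, tolerance = 1e-9)

  expect_error(isoEllipse(cbind(1:5, 2 * (1:5))), "singular")
})

test_that("ellipse membership matches the fitted quantile region", {
  withr::with_seed(12, pts <- MASS::mvrnorm(2000, c(0, 0),
                                            matrix(c(2, 0.8, 0.8, 1), 2)))
  e <- isoEllipse(pts, 0.9)
  inside <- ellipseContains(e, pts)
  md <- stats::mahalanobis(pts, colMeans(pts), cov(pts))
  expect_identical(unname(inside), unname(md <= qchisq(0.9, 2) + 1e-9))
})

test_that("kde2 is a normalised density with the expected modes", {
  withr::with_seed(5, pts <- cbind(rnorm(300, 10, 0.1), rnorm(300, 4, 0.1)))
  k <- kde2(pts)
  expect_equal(SporeHull:::kdeIntegral(k), 1, tolerance = 0.01)
  am <- which(k$z == max(k$z), arr.ind = TRUE)
  expect_equal(k$x[am[1]], mean(pts[, 1]), tolerance = diff(k$x[1:2]) * 1.5)
  expect_equal(k$y[am[2]], mean(pts[, 2]), tolerance = diff(k$y[1:2]) * 1.5)

  # two clusters ten bandwidths apart give two local maxima
  withr::with_seed(6, {
    two <- rbind(cbind(rnorm(200, 0, 0.5), rnorm(200, 0, 0.5)),
                 cbind(rnorm(200, 30, 0.5), rnorm(200, 30, 0.5)))
  })
  k2 <- kde2(two)
  at <- function(px, py) k2$z[which.min(abs(k2$x - px)),
                              which.min(abs(k2$y - py))]
  expect_gt(at(0, 0), 10 * at(15, 15))
  expect_gt(at(30, 30), 10 * at(15, 15))

  expect_error(kde2(cbind(1:5, rep(2, 5))), "variance")
})
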