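test_that("Q and apV follow their formulas", {
  m <- sporeMetrics(1, 1)
  expect_equal(m$Q, 1)
  expect_equal(m$apV, pi / 6)
  m2 <- sporeMetrics(12, 5)
  expect_equal(m2$Q, 2.4)
  expect_equal(m2$apV, 50 * pi)
  expect_error(sporeMetrics(-1, 2), "positive")
  expect_error(sporeMetrics(3, 0), "positive")
})

test_that("apV computed from species mean dimensions lands near the printed species mean", {
  # species-mean L and W give 188.5 µm³; the published per-spore mean is
  # 189.7 ± 29.1, so the plug-in value must fall within one SD
  apv <- sporeMetrics(12.67, 5.33)$apV
  expect_equal(apv, 188.5, tolerance = 0.001)
  expect_lt(abs(apv - 189.7), 29.1)
})

test_that("apV increases in each dimension", {
  for (L in c(8, 10, 12)) expect_true(all(diff(
    sporeMetrics(L, c(3, 4, 5))$apV) > 0))
  for (W in c(3, 4, 5)) expect_true(all(diff(
    sporeMetrics(c(8, 10, 12), W)$apV) > 0))
})

test_that("summaries are over collection means, not pooled spores", {
  df <- data.frame(collection_id = rep(c("a", "b", "c"), each = 2),
                   L = c(10, 10, 12, 12, 14, 14))
  s <- summarizeByCollection(df, "L")
  expect_equal(s@minimum, 10)
  expect_equal(s@mean, 12)
  expect_equal(s@sd, 2)  # sample SD of {10, 12, 14}
  expect_equal(s@maximum, 14)

  # unbalanced collections: collection-mean convention differs from pooling
  unb <- data.frame(collection_id = c("a", rep("b", 9)),
                    L = c(10, rep(14, 9)))
  s2 <- summarizeByCollection(unb, "L")
  expect_equal(s2@mean, 12)           # mean of {10, 14}
  expect_false(isTRUE(all.equal(s2@mean, mean(unb$L))))  # pooled 13.6
})

test_that("summary edge cases behave", {
  one <- data.frame(collection_id = "a", L = c(2, 4))
  s <- summarizeByCollection(one, "L")
  expect_identical(s@minimum, s@mean)
  expect_identical(s@mean, s@maximum)
  expect_true(is.na(s@sd))
  expect_match(formatSummary(s, digits = 0, unit = ""),
               "^\\(3\\) 3 \\(3\\)$")

  df <- data.frame(collection_id = rep(c("a", "b", "c"), 4), L = rnorm(12))
  shuffled <- df[sample(nrow(df)), ]
  expect_equal(summarizeByCollection(df, "L"),
               summarizeByCollection(shuffled, "L"))

  expect_error(summarizeByCollection(df[0, ], "L"), "empty")
  bad <- df; bad$collection_id[3] <- NA
  expect_error(summarizeByCollection(bad, "L"), "record")
})

test_that("description strings follow the published notation", {
  rs <- rangeSummary("L", 12.01, 12.67, 0.74, 13.63,
                     nCollections = 17L, nSpores = 703L, nBasidiomes = 14L)
  expect_identical(formatSummary(rs),
                   "[703/14/17] (12.01) 12.67 ± 0.74 (13.63) μm")
})

test_that("display rounding is decimal round-half-up", {
  expect_identical(SporeHull:::formatHalfUp(1.555, 2), "1.56")
  expect_identical(SporeHull:::formatHalfUp(2.675, 2), "2.68")
  expect_identical(SporeHull:::formatHalfUp(0.345, 2), "0.35")
  expect_identical(SporeHull:::formatHalfUp(-1.555, 2), "-1.56")
  expect_identical(SporeHull:::formatHalfUp(9.999, 2), "10.00")
  expect_identical(SporeHull:::formatHalfUp(2.5, 0), "3")
  expect_identical(SporeHull:::formatHalfUp(12.67, 2), "12.67")
})
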