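test_that("default zones partition the scorable intensity range", {
  z <- defaultZones()
  expect_equal(z$zone, scoreTiers())
  expect_equal(z$low, c(0L, 61L, 121L, 181L))
  expect_equal(z$high, c(60L, 120L, 180L, 235L))
  expect_equal(z$weight, c(4L, 3L, 2L, 1L))
  covered <- unlist(Map(seq, z$low, z$high))
  expect_equal(sort(covered), 0:235)   # no gaps, no overlaps
})

test_that("zone profile counts by inclusive bounds and conserves pixels", {
  dab <- matrix(30L, 10, 10)
  p <- zoneProfile(dab)
  expect_equal(unname(zoneCounts(p)), c(100, 0, 0, 0))
  expect_equal(excludedCount(p), 0)

  # boundary pixels 60 vs 61 split between adjacent zones
  dab <- matrix(c(rep(60L, 50), rep(61L, 50)), 10)
  p <- zoneProfile(dab)
  expect_equal(zoneCounts(p)[["high_positive"]], 50)
  expect_equal(zoneCounts(p)[["positive"]], 50)

  # the high-intensity band is excluded from scoring
  p <- zoneProfile(matrix(240L, 5, 5))
  expect_equal(totalScored(p), 0)
  expect_equal(excludedCount(p), 25)

  expect_error(zoneProfile(matrix(30L, 4, 4), mask = matrix(FALSE, 4, 4)),
               "empty selection")
  expect_error(zoneProfile(matrix(30L, 4, 4), mask = matrix(TRUE, 2, 2)),
               "mask")
})

test_that("zone counting equals a per-pixel reference loop", {
  z <- defaultZones()
  for (s in 1:20) {
    set.seed(s)
    dab <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32)
    p <- zoneProfile(dab, zones = z)
    ref <- naiveZoneCounts(as.vector(dab), z)
    expect_equal(zoneCounts(p), ref$zoneCounts)
    expect_equal(excludedCount(p), ref$excluded)
    expect_equal(sum(zoneCounts(p)) + excludedCount(p), 32 * 32)
    expect_equal(sum(intensityHistogram(p)), 32 * 32)
  }
})

profileFromPercents <- function(hp, p, lp, n, excluded = 0) {
  vals <- rep(c(30L, 90L, 150L, 208L, 248L), c(hp, p, lp, n, excluded))
  zoneProfile(matrix(vals, 1))
}

test_that("majority rule assigns the dominant zone directly", {
  r <- computeScore(profileFromPercents(70, 20, 10, 0))
  expect_equal(scoreLabel(r), "high_positive")
  expect_equal(r@decision, "majority_rule")
  expect_equal(numericScore(r), 4)

  # exactly 66% counts as majority (inclusive comparison)
  r <- computeScore(profileFromPercents(0, 66, 34, 0))
  expect_equal(r@decision, "majority_rule")
  expect_equal(scoreLabel(r), "positive")

  # 65% falls back to the weighted formula
  r <- computeScore(profileFromPercents(0, 65, 35, 0))
  expect_equal(r@decision, "weighted_formula")
})

test_that("weighted formula and its label mapping", {
  r <- computeScore(profileFromPercents(40, 30, 20, 10))
  expect_equal(numericScore(r), (40 * 4 + 30 * 3 + 20 * 2 + 10 * 1) / 100)
  expect_equal(scoreLabel(r), "positive")
  expect_equal(r@decision, "weighted_formula")
  expect_equal(sum(zonePercentages(r)), 100, tolerance = 1e-9)

  # single-zone degenerate case
  r <- computeScore(profileFromPercents(0, 0, 0, 100))
  expect_equal(numericScore(r), 1)
  expect_equal(scoreLabel(r), "negative")

  # nearest-weight mapping, ties rounding up towards the stronger tier
  r <- computeScore(profileFromPercents(50, 0, 0, 50))  # score 2.5
  expect_equal(numericScore(r), 2.5)
  expect_equal(scoreLabel(r), "positive")
  r <- computeScore(profileFromPercents(48, 0, 0, 52))  # score 2.44
  expect_equal(scoreLabel(r), "low_positive")

  # majority is judged on scored pixels: excluded pixels leave the
  # denominator entirely
  r <- computeScore(profileFromPercents(34, 0, 0, 16, 50))
  expect_equal(r@decision, "majority_rule")
  expect_equal(scoreLabel(r), "high_positive")
  expect_equal(r@excludedPercent, 50)

  expect_error(computeScore(zoneProfile(matrix(240L, 5, 5))),
               "no scorable pixels")
})

test_that("darkening scored pixels never decreases the numeric score", {
  set.seed(21)
  for (i in 1:10) {
    vals <- sample(0:235, 400, replace = TRUE)
    s0 <- numericScore(computeScore(zoneProfile(matrix(vals, 20))))
    shift <- sample(1:80, 1)
    s1 <- numericScore(computeScore(zoneProfile(
      matrix(pmax(vals - shift, 0L), 20))))
    expect_gte(s1, s0)
  }
})

test_that("end-to-end cytoplasmic scoring is deterministic and correct", {
  sp <- makeZoneMixture(c(high_positive = 1), size = 32, seed = 5)
  img <- renderSynthetic(sp)$image
  res <- scoreImage(img)
  expect_equal(scoreLabel(res$report), "high_positive")
  expect_true(all(res$dab[res$dab <= 235] <= 60))

  # bit-identical reports across runs: no hidden randomness
  res2 <- scoreImage(img)
  expect_identical(res$report, res2$report)
  expect_identical(res$profile, res2$profile)

  # an unstained background-only image has no scorable pixels
  bg <- array(255L, c(8, 8, 3))
  expect_error(scoreImage(bg), "no scorable pixels")
})
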