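test_that("OD transform matches the Beer-Lambert closed form", {
  px <- function(r, g, b) array(as.integer(c(r, g, b)), dim = c(1, 1, 3))
  expect_equal(rgbToOD(px(255, 255, 255))[1, 1, ], c(0, 0, 0))
  expect_equal(rgbToOD(px(26, 26, 26))[1, 1, ],
               rep(-log10(26 / 255), 3), tolerance = 1e-12)
  # fully dark pixels are floored at 1 count -> finite OD cap
  expect_equal(rgbToOD(px(0, 0, 0))[1, 1, ],
               rep(-log10(1 / 255), 3), tolerance = 1e-12)
  # pixels brighter than the background clamp to zero OD
  expect_equal(rgbToOD(px(255, 255, 255), background = c(200, 200, 200)),
               array(0, c(1, 1, 3)))
})

test_that("OD transform rejects malformed input", {
  expect_error(rgbToOD(matrix(1, 2, 2)), "H x W x 3")
  expect_error(rgbToOD(array(0L, c(2, 2, 4))), "3 channels")
  expect_error(rgbToOD(array(300L, c(1, 1, 3))), "8-bit")
  expect_error(rgbToOD(array(10L, c(1, 1, 3)), background = c(0, 255, 255)),
               "background")
})

test_that("stain system construction and its degenerate cases", {
  sys <- buildStainSystem(c(1, 0, 0), c(0, 1, 0))
  expect_equal(sys@complementary, c(0, 0, 1))
  expect_equal(unmixMatrix(sys), diag(3), ignore_attr = TRUE)

  hdab <- defaultStainSystem()
  expect_lt(max(abs(unmixMatrix(hdab) %*% stainMatrix(hdab) - diag(3))),
            1e-8)
  expect_true(validObject(hdab))

  expect_error(buildStainSystem(c(0.65, 0.70, 0.29), c(0.65, 0.70, 0.29)),
               "collinear")
  expect_error(buildStainSystem(c(0, 0, 0), c(0, 1, 0)), "non-zero")
})

test_that("unmixing recovers known densities and is linear", {
  sys <- defaultStainSystem()
  M <- stainMatrix(sys)
  # exact OD composed from known amounts: forward-inverse round trip
  od <- array(0, c(3, 4, 3))
  for (ch in 1:3) od[, , ch] <- 0.5 * M[1, ch] + 0.8 * M[2, ch]
  d <- deconvolve(od, sys)
  expect_equal(d$hematoxylin, matrix(0.5, 3, 4), tolerance = 1e-9)
  expect_equal(d$dab, matrix(0.8, 3, 4), tolerance = 1e-9)
  expect_equal(d$complementary, matrix(0, 3, 4), tolerance = 1e-9)

  # a pure-hematoxylin pixel carries no DAB
  odh <- array(rep(M[1, ], each = 1), c(1, 1, 3))
  expect_lt(abs(deconvolve(odh, sys)$dab[1, 1]), 1e-9)

  # random fields, exact linear path: property over 10 seeds
  for (s in 1:10) {
    set.seed(s)
    ah <- matrix(runif(64 * 64), 64)
    ad <- matrix(runif(64 * 64), 64)
    od <- array(0, c(64, 64, 3))
    for (ch in 1:3) od[, , ch] <- ah * M[1, ch] + ad * M[2, ch]
    d <- deconvolve(od, sys)
    expect_lt(max(abs(d$hematoxylin - ah)), 1e-6)
    expect_lt(max(abs(d$dab - ad)), 1e-6)
    # linearity: unmixing the OD sum equals the sum of unmixings
    d2 <- deconvolve(od + od, sys)
    expect_lt(max(abs(d2$dab - 2 * d$dab)), 1e-8)
  }
})

test_that("stain vector estimation round-trips the calibration model", {
  sys <- defaultStainSystem()
  dabv <- sys@dab

  # noise-free single-stain image returns the generating vector
  set.seed(11)
  ad <- matrix(runif(32 * 32, 0.3, 1), 32)
  img <- composeRGB(matrix(0, 32, 32), ad, quantize = FALSE)
  storage.mode(img) <- "double"
  est <- estimateStainVector(round(img))
  ang <- acos(min(sum(est * dabv), 1)) * 180 / pi
  expect_lt(ang, 0.5)   # quantization only

  # Monte-Carlo with channel noise sd 2: angular error < 2 degrees
  worst <- 0
  for (s in 1:100) {
    set.seed(s)
    ad <- matrix(runif(24 * 24, 0.3, 1), 24)
    img <- composeRGB(matrix(0, 24, 24), ad)
    noisy <- img + array(round(rnorm(length(img), 0, 2)), dim(img))
    noisy[] <- pmin(pmax(noisy, 0L), 255L)
    est <- estimateStainVector(noisy)
    worst <- max(worst, acos(min(sum(est * dabv), 1)) * 180 / pi)
  }
  expect_lt(worst, 2)

  # degenerate calibration: a background-only image has no direction
  bg <- array(255L, c(4, 4, 3))
  expect_error(estimateStainVector(bg), "degenerate")
  expect_error(estimateStainVector(bg, mask = matrix(FALSE, 4, 4)),
               "no pixels")
})

test_that("density display transform is monotone with known anchors", {
  expect_equal(densityToIntensity(matrix(0, 1))[1, 1], 255L)
  expect_equal(densityToIntensity(matrix(1, 1))[1, 1], 26L)
  # at the OD cap the formula evaluates to 1
  expect_equal(densityToIntensity(matrix(-log10(1 / 255), 1))[1, 1],
               round(255 * 10^(log10(1 / 255))))
  expect_equal(densityToIntensity(matrix(10, 1))[1, 1], 0L)
  # negative densities (unmixing noise) are treated as unstained
  expect_equal(densityToIntensity(matrix(-0.3, 1))[1, 1], 255L)
  d <- seq(0, 3, by = 0.01)
  v <- densityToIntensity(matrix(d, 1))
  expect_true(all(diff(as.vector(v)) <= 0))
})

test_that("complementary residual counts pixels and conserves totals", {
  img <- matrix(255L, 10, 10)
  res <- complementaryResidual(img)
  expect_equal(res$countAt255, 100)
  expect_equal(sum(res$histogram), 100)

  set.seed(4)
  img <- matrix(sample(0:255, 300, replace = TRUE), 15, 20)
  res <- complementaryResidual(img)
  expect_equal(sum(res$histogram), 300)
  expect_equal(res$countAt255, sum(img == 255L))
})

test_that("correct vectors empty the complementary channel; rotated ones do not", {
  sys <- defaultStainSystem()
  wrongSys <- rotateOffPlane(sys, 12)
  for (s in 1:20) {
    set.seed(100 + s)
    ah <- matrix(runif(48 * 48, 0.1, 0.6), 48)
    ad <- matrix(runif(48 * 48, 0.1, 0.6), 48)
    img <- composeRGB(ah, ad)
    od <- rgbToOD(img)
    compGood <- deconvolve(od, sys)$complementary
    compBad <- deconvolve(od, wrongSys)$complementary
    good <- complementaryResidual(densityToIntensity(compGood))$countAt255
    bad <- complementaryResidual(densityToIntensity(compBad))$countAt255
    expect_gt(good, bad)
    # mean residual density is likewise smaller with the true vectors
    expect_lt(mean(pmax(compGood, 0)), mean(pmax(compBad, 0)))
  }
})
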