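test_that("hex patch centers sit on a triangular lattice with the configured spacing", {
  img <- hexTestImage(seed = 1)  # 80 um spacing at 2 um/px -> 40 px
  cent <- blobCentroids(pixels(img))
  expect_gt(nrow(cent), 20)
  # interior blob nearest the frame center
  ctr <- c(127.5, 127.5)
  d2ctr <- sqrt((cent[, "x"] - ctr[1])^2 + (cent[, "y"] - ctr[2])^2)
  ref <- cent[which.min(d2ctr), ]
  d <- sqrt((cent[, "x"] - ref["x"])^2 + (cent[, "y"] - ref["y"])^2)
  nn6 <- sort(d[d > 1e-6])[1:6]
  expect_true(all(abs(nn6 - 40) < 0.5))
})

test_that("generators are bit-identical under a repeated seed", {
  expect_identical(pixels(hexTestImage(seed = 7, jitterUm = 4, noiseSd = 0.05)),
                   pixels(hexTestImage(seed = 7, jitterUm = 4, noiseSd = 0.05)))
  expect_identical(pixels(genScatteredImage(96, 96, seed = 3)),
                   pixels(genScatteredImage(96, 96, seed = 3)))
  base <- hexTestImage(seed = 1, widthPx = 96, heightPx = 96)
  expect_identical(pixels(genColocPair(base, 0.5, seed = 11)$ch2),
                   pixels(genColocPair(base, 0.5, seed = 11)$ch2))
  sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  expect_identical(coords(genPointPattern(sq, 500, seed = 4)),
                   coords(genPointPattern(sq, 500, seed = 4)))
})

test_that("invalid generator configurations raise named configuration errors", {
  expect_error(genHexPatchImage(latticeSpacingUm = 20, patchSigmaUm = 12),
               "2 \\* patchSigmaUm")
  expect_error(genHexPatchImage(pixelSizeUm = 20, latticeSpacingUm = 80,
                                patchSigmaUm = 12),
               "not resolvable in pixels")
  expect_error(genHexPatchImage(positionJitterUm = -1), "positionJitterUm")
  expect_error(genColocPair(hexTestImage(widthPx = 96, heightPx = 96), 1.2),
               "targetRho")
  band <- rectROI(0, 0, 64, 400)
  expect_error(genDvGradientMask(band, frontFraction = 1.5), "frontFraction")
  sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  expect_error(genPointPattern(sq, densityPerMm2 = -5), "densityPerMm2")
  bow <- cbind(c(0, 100, 100, 0), c(0, 100, 0, 100))  # self-intersecting
  expect_error(genPointPattern(bow, 100), "self-intersecting")
})

test_that("scattered blob counts follow the Poisson bound", {
  # estimate blob count from the integrated intensity (each bump integrates
  # to ~2*pi*sigma^2); expectation 200 blobs, bound 3*sqrt(200)
  sig <- 3
  for (s in 1:5) {
    img <- genScatteredImage(256, 256, pixelSizeUm = 2, patchSigmaUm = 2 * sig,
                             backgroundNoiseSd = 0, expectedCount = 200,
                             seed = s)
    est <- sum(pixels(img)) / (2 * pi * sig^2)
    expect_lt(abs(est - 200), 3 * sqrt(200))
  }
})

test_that("coloc pair reaches the target Pearson coefficient", {
  base <- hexTestImage(seed = 1)
  r1 <- corrCoef(spatialCrossCorrelation(base,
                                         genColocPair(base, 1, seed = 2)$ch2))
  expect_equal(r1, 1, tolerance = 1e-9)
  for (rho in c(0, 0.6)) {
    rs <- vapply(21:25, function(s) {
      corrCoef(spatialCrossCorrelation(
        base, genColocPair(base, rho, seed = s)$ch2))
    }, numeric(1))
    expect_lt(abs(mean(rs) - rho), 0.05)
  }
  flat <- Image2D(matrix(0.5, 32, 32), 2)
  expect_error(genColocPair(flat, 0.5), "constant")
})

test_that("dorsoventral gradient mask covers the configured dorsal fraction", {
  band <- rectROI(0, 0, 64, 400, dvAxis = c(0, 1))
  full <- genDvGradientMask(band, 1, frontSoftnessUm = 0, pixelSizeUm = 2)
  expect_true(all(pixels(full) > 0.25))
  none <- genDvGradientMask(band, 0, frontSoftnessUm = 0, pixelSizeUm = 2)
  expect_true(all(pixels(none) <= 0))
  half <- genDvGradientMask(band, 0.5, frontSoftnessUm = 0, pixelSizeUm = 2)
  expect_equal(mean(pixels(half) > 0.5), 0.5, tolerance = 0.01)
})

test_that("point patterns honour density, support and the Poisson bound", {
  sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))  # 1 mm^2
  expect_identical(length(genPointPattern(sq, 0, seed = 1)), 0L)
  for (s in 1:5) {
    pp <- genPointPattern(sq, 1000, seed = s)
    expect_lt(abs(length(pp) - 1000), 3 * sqrt(1000))
    expect_true(all(coords(pp)[, 1] >= 0 & coords(pp)[, 1] <= 1000))
  }
  # triangular region: all points inside the polygon
  tri <- cbind(c(0, 2000, 0), c(0, 0, 1500))
  pp <- genPointPattern(tri, 800, seed = 2)
  expect_true(all(mgcv::in.out(rbind(tri, tri[1, ]), coords(pp))))
  expect_equal(regionAreaMm2(pp), 1.5, tolerance = 1e-9)
})
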