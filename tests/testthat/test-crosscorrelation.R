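test_that("cross-correlation attains its analytic extremes", {
  img <- hexTestImage(seed = 1, widthPx = 96, heightPx = 96, noiseSd = 0.05)
  expect_equal(corrCoef(spatialCrossCorrelation(img, img)), 1,
               tolerance = 1e-12)
  neg <- Image2D(max(pixels(img)) - pixels(img), pixelSizeUm(img))
  expect_equal(corrCoef(spatialCrossCorrelation(img, neg)), -1,
               tolerance = 1e-12)
})

test_that("cross-correlation is symmetric in its arguments and affine-invariant", {
  a <- hexTestImage(seed = 2, widthPx = 96, heightPx = 96, noiseSd = 0.1)
  b <- genColocPair(a, 0.4, seed = 3)$ch2
  expect_identical(corrCoef(spatialCrossCorrelation(a, b)),
                   corrCoef(spatialCrossCorrelation(b, a)))
  expect_equal(corrCoef(spatialCrossCorrelation(linearAdjust(a, 12, 3), b)),
               corrCoef(spatialCrossCorrelation(a, b)), tolerance = 1e-9)
})

test_that("shape mismatches and constant channels are rejected", {
  a <- hexTestImage(seed = 1, widthPx = 64, heightPx = 64)
  b <- hexTestImage(seed = 1, widthPx = 64, heightPx = 48)
  expect_error(spatialCrossCorrelation(a, b), "identical shapes")
  flat <- Image2D(matrix(1, 64, 64), 2)
  expect_error(spatialCrossCorrelation(a, flat), "constant")
})

test_that("generator ground truth is recovered from the coloc construction", {
  base <- genHexPatchImage(256, 256, patchSigmaUm = 8, seed = 1)
  rs <- vapply(11:15, function(s) {
    corrCoef(spatialCrossCorrelation(base, genColocPair(base, 0.6,
                                                        seed = s)$ch2))
  }, numeric(1))
  expect_true(all(abs(rs - 0.6) < 0.05))
})

test_that("paired dorsal/ventral regions from one field agree with ground truth", {
  base <- genHexPatchImage(256, 512, patchSigmaUm = 8, seed = 4)
  pair <- genColocPair(base, 0.74, seed = 5)
  rois <- list(
    rectROI(0, 0, 256, 256, label = "dorsal", pairId = "s1"),
    rectROI(0, 256, 256, 512, label = "ventral", pairId = "s1"))
  res <- pairedDvCrossCorrelation(pair$ch1, pair$ch2, rois,
                                  markerPair = c("calbindin", "doublecortin"))
  expect_length(res, 2L)
  expect_true(all(vapply(res, function(x) x@paired, logical(1))))
  expect_true(all(abs(vapply(res, corrCoef, numeric(1)) - 0.74) < 0.06))
  tab <- crossCorrTable(res)
  expect_identical(tab$roi_label, c("dorsal", "ventral"))
  s <- dvSummary(tab)
  expect_identical(sort(s$roi_label), c("dorsal", "ventral"))
})

test_that("a lone region is flagged unpaired; unequal pairs are geometry errors", {
  base <- genHexPatchImage(128, 128, patchSigmaUm = 8, seed = 6)
  pair <- genColocPair(base, 0.5, seed = 7)
  res <- pairedDvCrossCorrelation(pair$ch1, pair$ch2,
                                  list(rectROI(0, 0, 64, 64,
                                               label = "dorsal",
                                               pairId = "s9")))
  expect_false(res[[1]]@paired)
  bad <- list(
    rectROI(0, 0, 64, 64, label = "dorsal", pairId = "p"),
    rectROI(0, 64, 64, 96, label = "ventral", pairId = "p"))
  expect_error(pairedDvCrossCorrelation(pair$ch1, pair$ch2, bad),
               "identical sizes")
})

test_that("a dorsal low-rho region orders below a ventral high-rho region", {
  ok <- 0L
  for (s in 1:6) {
    base <- genHexPatchImage(128, 128, patchSigmaUm = 8,
                             seed = deriveSeed(s, 1))
    d <- genColocPair(base, 0.15, seed = deriveSeed(s, 2))
    v <- genColocPair(base, 0.60, seed = deriveSeed(s, 3))
    rd <- corrCoef(spatialCrossCorrelation(d$ch1, d$ch2))
    rv <- corrCoef(spatialCrossCorrelation(v$ch1, v$ch2))
    ok <- ok + (rd < rv)
  }
  expect_identical(ok, 6L)
})
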