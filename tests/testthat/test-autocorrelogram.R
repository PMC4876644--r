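test_that("vectorized autocorrelogram matches the naive per-lag Pearson oracle", {
  set.seed(42)
  px <- matrix(stats::runif(24 * 24), 24, 24)
  img <- Image2D(px, 1)
  ac <- spatialAutocorrelogram(img, maxLag = 6, minOverlap = 20)
  oracle <- naiveAcorr(px, maxLag = 6, minOverlap = 20)
  expect_identical(lagCounts(ac), oracle$n)
  both <- lagValid(ac) & !is.na(oracle$r)
  expect_true(all(lagValid(ac) == !is.na(oracle$r)))
  expect_lt(max(abs(corrMap(ac)[both] - oracle$r[both])), 1e-10)

  # with a mask knocking out a corner block
  mask <- matrix(TRUE, 24, 24); mask[1:8, 1:8] <- FALSE
  acM <- spatialAutocorrelogram(Image2D(px, 1, mask = mask), maxLag = 6)
  oM <- naiveAcorr(px, mask, maxLag = 6)
  bothM <- lagValid(acM) & !is.na(oM$r)
  expect_lt(max(abs(corrMap(acM)[bothM] - oM$r[bothM])), 1e-10)
})

test_that("checkerboard correlation at unit lag is exactly -1", {
  cb <- outer(1:64, 1:64, function(i, j) (i + j) %% 2)
  ac <- spatialAutocorrelogram(Image2D(cb, 1), maxLag = 2)
  L <- maxLag(ac)
  expect_equal(corrMap(ac)[L + 1, L + 2], -1, tolerance = 1e-9)  # lag (1,0)
  expect_equal(corrMap(ac)[L + 2, L + 1], -1, tolerance = 1e-9)  # lag (0,1)
  expect_equal(corrMap(ac)[L + 2, L + 2], 1, tolerance = 1e-9)   # lag (1,1)
})

test_that("autocorrelogram invariants hold: r(0,0)=1, symmetry, range, overlap gating", {
  img <- hexTestImage(seed = 5, widthPx = 128, heightPx = 128,
                      jitterUm = 3, noiseSd = 0.05)
  ac <- spatialAutocorrelogram(img, maxLag = 60)
  L <- maxLag(ac)
  r <- corrMap(ac)
  expect_equal(r[L + 1, L + 1], 1, tolerance = 1e-9)
  expect_true(all(abs(r[lagValid(ac)]) <= 1))
  flip <- r[rev(seq_len(nrow(r))), rev(seq_len(ncol(r)))]
  both <- lagValid(ac) & lagValid(ac)[rev(seq_len(nrow(r))), rev(seq_len(ncol(r)))]
  expect_identical(r[both], flip[both])
  # n < minOverlap lags are never valid: near-full-size lags on a small
  # image leave overlaps below 20 pixels
  set.seed(1)
  small <- Image2D(matrix(stats::runif(900), 30, 30), 1)
  acS <- spatialAutocorrelogram(small, maxLag = 28)
  expect_true(any(lagCounts(acS) < 20))
  expect_false(any(lagValid(acS)[lagCounts(acS) < 20]))
})

test_that("degenerate inputs and bad parameters are rejected", {
  expect_error(spatialAutocorrelogram(Image2D(matrix(3, 32, 32), 1)),
               "constant")
  img <- hexTestImage(seed = 1, widthPx = 64, heightPx = 64)
  expect_error(spatialAutocorrelogram(img, maxLag = 64), "maxLag")
  # zero-variance windows (blank margin) are flagged, not zero-filled
  px <- matrix(0, 40, 40)
  px[15:26, 15:26] <- matrix(stats::runif(144), 12, 12)
  ac <- spatialAutocorrelogram(Image2D(px, 1), maxLag = 30)
  expect_true(any(!lagValid(ac)))
  expect_true(all(is.na(corrMap(ac)[!lagValid(ac)])))
})

test_that("hex-lattice autocorrelogram shows six first-ring peaks at the lattice spacing", {
  img <- hexTestImage(seed = 1)  # spacing 40 px
  ac <- spatialAutocorrelogram(img, maxLag = 60)
  pk <- findAcorrPeaks(ac)
  pk <- pk[pk[, "radius"] > 10, , drop = FALSE]
  six <- pk[order(pk[, "radius"]), , drop = FALSE][1:6, ]
  expect_true(all(abs(six[, "radius"] - 40) <= 1))
  ang <- sort(atan2(six[, "tauY"], six[, "tauX"]) * 180 / pi)
  gaps <- diff(c(ang, ang[1] + 360))
  expect_true(all(abs(gaps - 60) <= 5))
})

test_that("the autocorrelogram is invariant to positive-gain linear adjustment", {
  img <- hexTestImage(seed = 6, widthPx = 96, heightPx = 96, noiseSd = 0.05)
  a0 <- spatialAutocorrelogram(img, maxLag = 40)
  a1 <- spatialAutocorrelogram(linearAdjust(img, gain = 250, offset = 40),
                               maxLag = 40)
  expect_identical(lagValid(a0), lagValid(a1))
  expect_lt(max(abs(corrMap(a0) - corrMap(a1)), na.rm = TRUE), 1e-9)
})

test_that("autocorrelogram maps round-trip through their TIFF export", {
  ac <- spatialAutocorrelogram(hexTestImage(seed = 1, widthPx = 96,
                                            heightPx = 96), maxLag = 30)
  prefix <- withr::local_tempfile()
  paths <- writeAutocorrelogram(ac, prefix)
  stored <- tiff::readTIFF(paths[1])
  valid <- tiff::readTIFF(paths[2]) > 0
  expect_identical(valid, lagValid(ac))
  expect_lt(max(abs((2 * stored[valid] - 1) - corrMap(ac)[valid])), 1e-6)
})
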