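test_that("16-bit TIFF round trip preserves the stored grid bit-for-bit", {
  img <- hexTestImage(seed = 1, widthPx = 64, heightPx = 64, noiseSd = 0.05)
  path <- withr::local_tempfile(fileext = ".tif")
  writeImage(img, path)
  back <- readImage(path)  # pixel size from sidecar
  expect_equal(pixelSizeUm(back), 2)
  expect_identical(pixels(back), floor(pixels(img) * 65535))
  # a second write/read cycle is exactly stable
  path2 <- withr::local_tempfile(fileext = ".tif")
  writeImage(Image2D(pixels(back) / 65535, 2), path2)
  expect_identical(pixels(readImage(path2, 2)), pixels(back))
})

test_that("multi-channel files and missing pixel sizes are rejected", {
  rgb <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(stats::runif(64 * 3), c(8, 8, 3)), rgb)
  expect_error(readImage(rgb, 2), "multi-channel")
  gray <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(stats::runif(64), 8, 8), gray)
  expect_error(readImage(gray), "pixel size missing")
  expect_s4_class(readImage(gray, pixelSizeUm = 1.5), "Image2D")
})

test_that("8-bit and 16-bit encodings of one pattern give identical autocorrelograms", {
  # a pattern already quantized to 8 bits, so both files encode affine maps
  # of the same grid and Pearson statistics must agree
  img <- hexTestImage(seed = 2, widthPx = 96, heightPx = 96, noiseSd = 0.1)
  q8 <- floor(pixels(img) * 255) / 255
  p8 <- withr::local_tempfile(fileext = ".png")
  p16 <- withr::local_tempfile(fileext = ".tif")
  png::writePNG(q8, p8)
  tiff::writeTIFF(q8, p16, bits.per.sample = 16L)
  a8 <- corrMap(spatialAutocorrelogram(readImage(p8, 2), maxLag = 30))
  a16 <- corrMap(spatialAutocorrelogram(readImage(p16, 2), maxLag = 30))
  expect_lt(max(abs(a8 - a16), na.rm = TRUE), 1e-6)
})

test_that("ROI extraction crops half-open rectangles and masks polygons", {
  img <- hexTestImage(seed = 3, widthPx = 64, heightPx = 48)
  whole <- extractRoi(img, rectROI(0, 0, 64, 48))
  expect_identical(pixels(whole), pixels(img))
  a <- extractRoi(img, rectROI(2, 4, 34, 36, label = "dorsal"))
  b <- extractRoi(img, rectROI(30, 10, 62, 42, label = "ventral"))
  expect_identical(dim(a), dim(b))  # paired crops share a shape
  expect_identical(dim(a), c(32L, 32L))
  expect_error(extractRoi(img, rectROI(40, 0, 70, 10)), "exceeds image bounds")

  # triangle mask: pixel-center rasterization oracle via half-plane tests
  tri <- rbind(c(5, 5), c(45, 5), c(5, 40))
  crop <- extractRoi(img, polygonROI(tri))
  d <- dim(crop)
  bb <- c(5, 5)
  inTri <- function(x, y) {
    s1 <- (45 - 5) * (y - 5) - (5 - 5) * (x - 5)
    s2 <- (5 - 45) * (y - 5) - (40 - 5) * (x - 45)
    s3 <- (5 - 5) * (y - 40) - (5 - 40) * (x - 5)
    (s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0)
  }
  oracle <- 0L
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      oracle <- oracle + inTri(bb[1] + j - 0.5, bb[2] + i - 0.5)
    }
  }
  expect_identical(sum(validMask(crop)), as.integer(oracle))
  expect_equal(sum(validMask(crop)), 0.5 * 40 * 35, tolerance = 0.1)
})

test_that("linear adjustment is recorded, gated on gain, and Pearson-invariant", {
  img <- hexTestImage(seed = 4, widthPx = 64, heightPx = 64, noiseSd = 0.05)
  expect_identical(pixels(linearAdjust(img, 1, 0)), pixels(img))
  const5 <- Image2D(matrix(5, 8, 8), 1)
  expect_identical(pixels(linearAdjust(const5, 2, 10)),
                   matrix(20, 8, 8))
  expect_error(linearAdjust(img, 0, 1), "gain must be > 0")
  expect_error(linearAdjust(img, -2, 1), "gain must be > 0")
  adj <- linearAdjust(img, 3.7, 12)
  expect_length(adj@meta$adjustments, 1L)
  a0 <- corrMap(spatialAutocorrelogram(img, maxLag = 20))
  a1 <- corrMap(spatialAutocorrelogram(adj, maxLag = 20))
  expect_lt(max(abs(a0 - a1), na.rm = TRUE), 1e-9)
})

test_that("ROI sets and point tables round-trip through their text formats", {
  rois <- list(
    d1 = rectROI(0, 0, 32, 32, dvAxis = c(0, 1), label = "dorsal",
                 pairId = "s1"),
    v1 = rectROI(0, 96, 32, 128, dvAxis = c(0, 1), label = "ventral",
                 pairId = "s1"),
    pol = polygonROI(rbind(c(1, 1), c(20, 2), c(10, 18)), label = "whole"))
  path <- withr::local_tempfile(fileext = ".yaml")
  writeRois(rois, path)
  back <- readRois(path)
  expect_identical(names(back), names(rois))
  expect_identical(back$d1@coords, rois$d1@coords)
  expect_identical(back$d1@pairId, "s1")
  expect_equal(back$pol@vertices, rois$pol@vertices)

  sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  pp <- genPointPattern(sq, 300, marker = "calbindin", seed = 9)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writePointPattern(pp, tsv, regionName = "mec_l3")
  header <- readLines(tsv, n = 1)
  expect_identical(header, "x_um\ty_um\tmarker\tregion")
  back <- readPointPattern(tsv)
  expect_equal(coords(back), coords(pp))
  expect_identical(marker(back), "calbindin")
})
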