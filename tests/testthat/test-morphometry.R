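sqPoly <- function(w = 1000, h = 1000) cbind(c(0, w, w, 0), c(0, 0, h, h))

test_that("cell density is exact count/area arithmetic", {
  reg <- sqPoly(316.227766, 316.227766)  # 0.1 mm^2
  pts <- cbind(runif(100, 1, 315), runif(100, 1, 315))
  d <- cellDensity(PointPattern(pts, "calbindin", reg))
  expect_identical(d$count, 100L)
  expect_equal(d$density, 100 / d$area_mm2, tolerance = 0)
  expect_equal(d$density, 1000, tolerance = 1e-6)
  empty <- PointPattern(matrix(numeric(0), 0, 2), "calbindin", sqPoly())
  expect_identical(cellDensity(empty)$density, 0)
  # degenerate (zero-area) regions cannot even be constructed
  expect_error(PointPattern(matrix(numeric(0), 0, 2), "x",
                            cbind(c(0, 1, 2), c(0, 0, 0))),
               "regionAreaMm2|area")
})

test_that("cell density is invariant under rigid motion of pattern and region", {
  pp <- genPointPattern(sqPoly(), 800, seed = 3)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shift <- c(500, -200)
  rot <- function(m) sweep(m %*% t(R), 2, shift, "+")
  moved <- PointPattern(rot(coords(pp)), marker(pp), rot(regionPolygon(pp)))
  expect_identical(cellDensity(moved)$count, cellDensity(pp)$count)
  expect_equal(cellDensity(moved)$density, cellDensity(pp)$density,
               tolerance = 1e-9)
})

test_that("mean density over seeded sections recovers the generator intensity", {
  dens <- vapply(1:20, function(s) {
    cellDensity(genPointPattern(sqPoly(), 1000, seed = s))$density
  }, numeric(1))
  sem <- sd(dens) / sqrt(length(dens))
  expect_lt(abs(mean(dens) - 1000), 3 * sem)
})

test_that("dorsoventral thirds conserve counts and recover uniform proportions", {
  pp <- genPointPattern(sqPoly(), 3000, seed = 11)  # ~3000 points
  part <- dvPartition(pp, c(0, 1))
  expect_identical(part$bin, c("dorsal", "intermediate", "ventral"))
  expect_identical(sum(part$count), length(pp))
  expect_equal(sum(part$proportion), 1, tolerance = 1e-9)
  expect_true(all(abs(part$proportion - 1 / 3) < 0.05))
  expect_error(dvPartition(pp, c(0, 0)), "degenerate")
})

test_that("a gradient with third-density ratio 1:2:3 is recovered", {
  # slope 1.5 on the normalized axis puts the three equal-extent thirds at
  # relative densities 0.5:1:1.5
  pp <- genPointPattern(sqPoly(1500, 2000), 1200, dvGradientSlope = 1.5,
                        seed = 21)
  part <- dvPartition(pp, c(0, 1))
  expect_true(all(abs(part$proportion - c(1, 2, 3) / 6) < 0.05))
  # all mass in the dorsal third
  dors <- PointPattern(cbind(runif(200, 10, 990), runif(200, 10, 320)),
                       "x", sqPoly())
  expect_equal(dvPartition(dors, c(0, 1))$proportion, c(1, 0, 0))
})

test_that("partition respects an oblique dorsoventral axis", {
  pp <- genPointPattern(sqPoly(), 2000, dvGradientSlope = 1.5,
                        dvAxis = c(1, 1), seed = 31)
  part <- dvPartition(pp, c(1, 1))
  expect_identical(sum(part$count), length(pp))
  expect_gt(part$proportion[3], part$proportion[1])
  expect_equal(sum(part$area_mm2), regionAreaMm2(pp), tolerance = 1e-6)
})

test_that("density trajectories summarize groups in order", {
  one <- densityTrajectory(list(P4 = 955))
  expect_identical(one$mean_density, 955)
  expect_identical(one$sd_density, 0)
  groups <- lapply(c(`P4-P8` = 955, `P12-P16` = 333, adult = 141),
                   function(d) {
                     do.call(rbind, lapply(1:8, function(s) {
                       cellDensity(genPointPattern(sqPoly(), d,
                                                   seed = deriveSeed(d, s)))
                     }))
                   })
  traj <- densityTrajectory(groups)
  expect_identical(as.character(traj$group), c("P4-P8", "P12-P16", "adult"))
  expect_true(all(abs(traj$mean_density - c(955, 333, 141)) /
                  c(955, 333, 141) < 0.10))
  expect_true(all(diff(traj$mean_density) < 0))
  # permuting sections within a group leaves the summary unchanged
  perm <- groups
  perm[[1]] <- perm[[1]][sample(8), ]
  expect_equal(densityTrajectory(perm)$mean_density, traj$mean_density)
  expect_error(densityTrajectory(list(P4 = numeric(0))), "empty group")
})

test_that("marker extent fraction recovers the expression front", {
  band <- rectROI(0, 0, 64, 400, dvAxis = c(0, 1))
  bright <- Image2D(matrix(0.9, 400, 64), 2)
  expect_identical(markerExtentFraction(bright, band, threshold = 0.5)$fraction, 1)
  dark <- Image2D(matrix(0.05, 400, 64), 2)
  expect_identical(markerExtentFraction(dark, band, threshold = 0.5)$fraction, 0)
  img <- genDvGradientMask(band, 0.4, frontSoftnessUm = 4, pixelSizeUm = 2)
  ef <- markerExtentFraction(img, band)  # Otsu threshold
  expect_lt(abs(ef$fraction - 0.40), 0.02)
  expect_equal(ef$band_length_um, 400 * 2, tolerance = 2)
  short <- rectROI(0, 0, 64, 40, dvAxis = c(0, 1))
  expect_error(markerExtentFraction(Image2D(matrix(0.5, 40, 64), 2), short),
               "at least 50 px")
})

test_that("extent fraction is monotone in the generated front fraction", {
  band <- rectROI(0, 0, 64, 400, dvAxis = c(0, 1))
  fr <- vapply(seq(0.1, 1, by = 0.15), function(f) {
    img <- genDvGradientMask(band, f, frontSoftnessUm = 4, pixelSizeUm = 2)
    markerExtentFraction(img, band, threshold = 0.5)$fraction
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})
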