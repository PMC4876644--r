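# Synthetic-histology generators. Each generator is a pure function of its
# arguments including the seed, renders float intensities in [0, 1], and
# provides known ground truth (lattice spacing, Pearson coefficient, cell
# density, expression-front position) for parameter-recovery tests.

.checkSynthConfig <- function(widthPx, heightPx, pixelSizeUm, spacingUm,
                              sigmaUm, jitterUm, noiseSd) {
  if (widthPx < 1 || heightPx < 1) {
    stop("configuration error: image dimensions must be positive")
  }
  if (!(pixelSizeUm > 0)) {
    stop("configuration error: pixelSizeUm must be > 0")
  }
  if (!(spacingUm > 2 * sigmaUm)) {
    stop("configuration error: latticeSpacingUm must exceed 2 * patchSigmaUm ",
         "(patches not resolvable)")
  }
  if (spacingUm / pixelSizeUm < 6) {
    stop("configuration error: latticeSpacingUm / pixelSizeUm must be >= 6 ",
         "(spacing not resolvable in pixels)")
  }
  if (jitterUm < 0) stop("configuration error: positionJitterUm must be >= 0")
  if (noiseSd < 0) stop("configuration error: backgroundNoiseSd must be >= 0")
  invisible(TRUE)
}

# Render unit-amplitude isotropic Gaussian bumps at the given centers
# (pixel coordinates, columns x, y; 0-based pixel-center convention).
.renderBumpImage <- function(centers, sigmaPx, nrow, ncol) {
  img <- matrix(0, nrow, ncol)
  if (is.null(centers) || nrow(centers) == 0L) return(img)
  w <- ceiling(4 * sigmaPx)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    x0 <- max(0L, floor(cx) - w); x1 <- min(ncol - 1L, ceiling(cx) + w)
    y0 <- max(0L, floor(cy) - w); y1 <- min(nrow - 1L, ceiling(cy) + w)
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    gx <- exp(-(xs - cx)^2 / (2 * sigmaPx^2))
    gy <- exp(-(ys - cy)^2 / (2 * sigmaPx^2))
    img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + outer(gy, gx)
  }
  img
}

.hexCenters <- function(widthPx, heightPx, spacingPx, orientationDeg) {
  th <- orientationDeg * pi / 180
  a1 <- spacingPx * c(cos(th), sin(th))
  a2 <- spacingPx * c(cos(th + pi / 3), sin(th + pi / 3))
  ctr <- c((widthPx - 1) / 2, (heightPx - 1) / 2)
  nmax <- ceiling(sqrt(widthPx^2 + heightPx^2) / spacingPx) + 2L
  ij <- expand.grid(i = -nmax:nmax, j = -nmax:nmax)
  cx <- ctr[1] + ij$i * a1[1] + ij$j * a2[1]
  cy <- ctr[2] + ij$i * a1[2] + ij$j * a2[2]
  margin <- spacingPx
  keep <- cx > -margin & cx < widthPx - 1 + margin &
          cy > -margin & cy < heightPx - 1 + margin
  cbind(x = cx[keep], y = cy[keep])
}

#' Generate a hexagonal-lattice patch image
#'
#' Renders bright Gaussian-profile patches whose centers sit on a triangular
#' (hexagonal-neighbor) lattice with the configured center-to-center spacing
#' and orientation, emulating the periodic arrangement of calbindin-positive
#' patches seen in tangential sections of layer 2. Optional isotropic
#' Gaussian positional jitter and additive background noise; intensities are
#' clamped to [0, 1]. The same arguments and seed always yield a
#' bit-identical image.
#'
#' @param widthPx,heightPx image dimensions in pixels.
#' @param pixelSizeUm pixel size in micrometres per pixel (> 0).
#' @param latticeSpacingUm center-to-center patch spacing in micrometres;
#'   must exceed `2 * patchSigmaUm` and be at least 6 pixels.
#' @param patchSigmaUm Gaussian patch radius (sigma) in micrometres.
#' @param latticeOrientationDeg lattice orientation in degrees.
#' @param positionJitterUm standard deviation of isotropic Gaussian jitter of
#'   patch centers, micrometres (>= 0).
#' @param backgroundNoiseSd standard deviation of additive intensity noise
#'   (>= 0; intensity units on the [0, 1] scale).
#' @param seed integer seed.
#' @return An [Image2D-class]; `meta$generator` records all settings.
#' @examples
#' img <- genHexPatchImage(128, 128, pixelSizeUm = 2, latticeSpacingUm = 80,
#'                         patchSigmaUm = 12, seed = 1)
#' @export
genHexPatchImage <- function(widthPx = 256, heightPx = 256, pixelSizeUm = 2,
                             latticeSpacingUm = 80, patchSigmaUm = 12,
                             latticeOrientationDeg = 0, positionJitterUm = 0,
                             backgroundNoiseSd = 0.02, seed = 1) {
  .checkSynthConfig(widthPx, heightPx, pixelSizeUm, latticeSpacingUm,
                    patchSigmaUm, positionJitterUm, backgroundNoiseSd)
  sPx <- latticeSpacingUm / pixelSizeUm
  sigPx <- patchSigmaUm / pixelSizeUm
  jitPx <- positionJitterUm / pixelSizeUm
  centers <- .hexCenters(widthPx, heightPx, sPx, latticeOrientationDeg)
  px <- .withSeed(seed, {
    if (jitPx > 0) {
      centers <- centers + matrix(stats::rnorm(2 * nrow(centers), sd = jitPx),
                                  ncol = 2)
    }
    img <- .renderBumpImage(centers, sigPx, heightPx, widthPx)
    img <- pmin(img, 1)
    if (backgroundNoiseSd > 0) {
      img <- img + matrix(stats::rnorm(length(img), sd = backgroundNoiseSd),
                          heightPx, widthPx)
    }
    pmin(pmax(img, 0), 1)
  })
  Image2D(px, pixelSizeUm,
          meta = list(generator = list(
            type = "hex_patch", width_px = widthPx, height_px = heightPx,
            pixel_size_um = pixelSizeUm, lattice_spacing_um = latticeSpacingUm,
            patch_sigma_um = patchSigmaUm,
            lattice_orientation_deg = latticeOrientationDeg,
            position_jitter_um = positionJitterUm,
            background_noise_sd = backgroundNoiseSd, seed = seed)))
}

#' Generate a scattered (non-periodic) patch image
#'
#' Renders Gaussian blobs whose centers are drawn from a homogeneous Poisson
#' process over the frame, emulating the non-periodic arrangement of
#' reelin-positive cells. The expected blob count defaults to the density of
#' a hexagonal lattice with the configured spacing (one blob per unit cell of
#' area `spacing^2 * sin 60`), making the image directly comparable to
#' [genHexPatchImage()] at matched density; pass `expectedCount` to override
#' (0 yields pure background noise).
#'
#' @inheritParams genHexPatchImage
#' @param expectedCount expected number of blobs; `NULL` derives it from
#'   `latticeSpacingUm` as above.
#' @return An [Image2D-class].
#' @examples
#' img <- genScatteredImage(128, 128, pixelSizeUm = 2, seed = 3)
#' @export
genScatteredImage <- function(widthPx = 256, heightPx = 256, pixelSizeUm = 2,
                              latticeSpacingUm = 80, patchSigmaUm = 12,
                              backgroundNoiseSd = 0.02, expectedCount = NULL,
                              seed = 1) {
  .checkSynthConfig(widthPx, heightPx, pixelSizeUm, latticeSpacingUm,
                    patchSigmaUm, 0, backgroundNoiseSd)
  sPx <- latticeSpacingUm / pixelSizeUm
  sigPx <- patchSigmaUm / pixelSizeUm
  if (is.null(expectedCount)) {
    expectedCount <- widthPx * heightPx / (sPx^2 * sin(pi / 3))
  }
  if (expectedCount < 0) {
    stop("configuration error: expectedCount must be >= 0")
  }
  px <- .withSeed(seed, {
    nBlob <- stats::rpois(1, expectedCount)
    centers <- cbind(x = stats::runif(nBlob, -0.5, widthPx - 0.5),
                     y = stats::runif(nBlob, -0.5, heightPx - 0.5))
    img <- pmin(.renderBumpImage(centers, sigPx, heightPx, widthPx), 1)
    if (backgroundNoiseSd > 0) {
      img <- img + matrix(stats::rnorm(length(img), sd = backgroundNoiseSd),
                          heightPx, widthPx)
    }
    pmin(pmax(img, 0), 1)
  })
  Image2D(px, pixelSizeUm,
          meta = list(generator = list(
            type = "scattered", width_px = widthPx, height_px = heightPx,
            pixel_size_um = pixelSizeUm, patch_sigma_um = patchSigmaUm,
            expected_count = expectedCount,
            background_noise_sd = backgroundNoiseSd, seed = seed)))
}

#' Generate a colocalized channel pair with known Pearson coefficient
#'
#' Shared-component construction of a second channel from a base channel:
#' with `z` the standardized base image and `eps` independent standardized
#' noise, the raw second channel is `rho * z + sqrt(1 - rho^2) * eps`, whose
#' Pearson correlation with the base is `targetRho` in expectation. The raw
#' channel is mapped back to nonnegative [0, 1] intensities by a positive
#' affine map, which leaves the Pearson coefficient unchanged. This provides
#' exact ground truth for [spatialCrossCorrelation()].
#'
#' @param base an [Image2D-class]; must be non-constant over valid pixels.
#' @param targetRho target Pearson correlation in [-1, 1].
#' @param noiseSd standard deviation of the raw independent noise before
#'   standardization (> 0; the value does not affect the statistics and is
#'   kept for provenance).
#' @param seed integer seed.
#' @return A list with elements `ch1` (the base) and `ch2` (an
#'   [Image2D-class] with the same pixel size and mask).
#' @examples
#' base <- genHexPatchImage(128, 128, seed = 1)
#' pair <- genColocPair(base, targetRho = 0.6, seed = 2)
#' corrCoef(spatialCrossCorrelation(pair$ch1, pair$ch2))
#' @export
genColocPair <- function(base, targetRho, noiseSd = 1, seed = 1) {
  stopifnot(is(base, "Image2D"))
  if (abs(targetRho) > 1) {
    stop("configuration error: |targetRho| must be <= 1")
  }
  if (!(noiseSd > 0)) stop("configuration error: noiseSd must be > 0")
  v <- base@pixels[base@mask]
  s <- stats::sd(v)
  if (!(s > 0)) stop("degenerate input: base image is constant")
  z <- (base@pixels - mean(v)) / s
  z[!base@mask] <- 0
  raw <- .withSeed(seed, {
    eps <- matrix(stats::rnorm(length(z), sd = noiseSd), nrow(z), ncol(z))
    ev <- eps[base@mask]
    eps <- (eps - mean(ev)) / stats::sd(ev)
    targetRho * z + sqrt(1 - targetRho^2) * eps
  })
  rv <- raw[base@mask]
  lo <- min(rv); hi <- max(rv)
  scaled <- if (hi > lo) (raw - lo) / (hi - lo) else raw * 0
  scaled[!base@mask] <- 0
  ch2 <- Image2D(scaled, base@pixelSizeUm, mask = base@mask,
                 meta = list(generator = list(
                   type = "coloc_pair", target_rho = targetRho,
                   noise_sd = noiseSd, seed = seed)))
  list(ch1 = base, ch2 = ch2)
}

#' Generate a dorsoventral expression-front image over a band ROI
#'
#' Emulates a marker (such as wolframin) whose expression covers the dorsal
#' fraction of a band-shaped region: intensity is a sigmoid front along the
#' band's dorsoventral axis, equal to 1 well dorsal of the front and 0 well
#' ventral of it, crossing 0.5 at `frontFraction` of the band's dorsoventral
#' extent. `frontSoftnessUm = 0` gives a hard step. The returned image covers
#' the band's bounding box (its frame origin at the box corner); polygon
#' bands get a validity mask.
#'
#' @param band an [ROI-class] with a declared dorsoventral axis.
#' @param frontFraction fraction in [0, 1] of the dorsoventral extent that
#'   expresses the marker, counted from the dorsal end.
#' @param frontSoftnessUm sigmoid edge scale in micrometres (>= 0).
#' @param pixelSizeUm pixel size of the rendered image.
#' @return An [Image2D-class]; `meta$generator` records the settings and the
#'   bounding-box origin (`origin_px`) relative to the ROI's frame.
#' @examples
#' band <- rectROI(0, 0, 64, 400, dvAxis = c(0, 1))
#' img <- genDvGradientMask(band, frontFraction = 0.4, frontSoftnessUm = 4,
#'                          pixelSizeUm = 2)
#' @export
genDvGradientMask <- function(band, frontFraction, frontSoftnessUm = 0,
                              pixelSizeUm = 2) {
  stopifnot(is(band, "ROI"))
  if (frontFraction < 0 || frontFraction > 1) {
    stop("configuration error: frontFraction must lie in [0, 1]")
  }
  if (frontSoftnessUm < 0) {
    stop("configuration error: frontSoftnessUm must be >= 0")
  }
  bb <- .roiBoundingBox(band)
  w <- as.integer(ceiling(bb[3] - bb[1]))
  h <- as.integer(ceiling(bb[4] - bb[2]))
  # pixel centers of the rendered frame, in the ROI's pixel coordinates
  xs <- bb[1] + (seq_len(w) - 0.5)
  ys <- bb[2] + (seq_len(h) - 0.5)
  PX <- matrix(xs, h, w, byrow = TRUE)
  PY <- matrix(ys, h, w)
  t <- (PX * band@dvAxis[1] + PY * band@dvAxis[2]) * pixelSizeUm
  mask <- matrix(TRUE, h, w)
  if (band@kind == "polygon") {
    mask <- matrix(.pointsInPolygon(cbind(as.vector(PX), as.vector(PY)),
                                    band@vertices), h, w)
  }
  tv <- t[mask]
  t0 <- min(tv); L <- max(tv) - t0
  d <- t - t0
  # frontFraction 1 covers the whole band including its ventral edge pixel
  d0 <- if (frontFraction >= 1) Inf else frontFraction * L
  px <- if (frontSoftnessUm == 0) {
    (d < d0) * 1
  } else if (is.infinite(d0)) {
    matrix(1, nrow(d), ncol(d))
  } else {
    1 / (1 + exp((d - d0) / frontSoftnessUm))
  }
  px[!mask] <- 0
  Image2D(px, pixelSizeUm, mask = mask,
          meta = list(generator = list(
            type = "dv_gradient", front_fraction = frontFraction,
            front_softness_um = frontSoftnessUm, pixel_size_um = pixelSizeUm,
            origin_px = c(bb[1], bb[2]))))
}

#' Generate a point pattern with optional dorsoventral density gradient
#'
#' Draws cell positions from an inhomogeneous Poisson process inside a simple
#' polygon (micrometre coordinates): the local intensity is
#' `densityPerMm2 * (1 + dvGradientSlope * (t - 1/2))`, clipped at zero,
#' where `t` in [0, 1] is the normalized position along the dorsoventral
#' axis. With zero slope the expected count is exactly
#' `densityPerMm2 * area`. Sampling is by rejection inside the polygon's
#' bounding box, so the support is exactly the polygon.
#'
#' @param regionPolygonUm k x 2 matrix of simple-polygon vertices in
#'   micrometres.
#' @param densityPerMm2 mean cell density in cells per mm^2 (>= 0).
#' @param dvGradientSlope relative density change per normalized
#'   dorsoventral unit (slope 1.5 yields third-densities in ratio 1:2:3).
#' @param dvAxis dorsoventral axis direction (normalized internally).
#' @param marker marker name recorded on the pattern.
#' @param seed integer seed.
#' @return A [PointPattern-class].
#' @examples
#' sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
#' pp <- genPointPattern(sq, densityPerMm2 = 500, seed = 1)
#' cellDensity(pp)
#' @export
genPointPattern <- function(regionPolygonUm, densityPerMm2,
                            dvGradientSlope = 0, dvAxis = c(0, 1),
                            marker = "synthetic", seed = 1) {
  poly <- as.matrix(regionPolygonUm)
  if (!.polyIsSimple(poly)) {
    stop("geometry error: region polygon is self-intersecting")
  }
  if (densityPerMm2 < 0) {
    stop("configuration error: densityPerMm2 must be >= 0")
  }
  dvAxis <- as.numeric(dvAxis)
  dvAxis <- dvAxis / sqrt(sum(dvAxis^2))
  tAll <- .projectOnAxis(poly, dvAxis)
  t0 <- min(tAll); t1 <- max(tAll)
  dens <- function(t) {
    tn <- if (t1 > t0) (t - t0) / (t1 - t0) else rep(0.5, length(t))
    pmax(1 + dvGradientSlope * (tn - 0.5), 0)
  }
  relMax <- max(dens(c(t0, t1)), 1e-12)
  bb <- c(min(poly[, 1]), min(poly[, 2]), max(poly[, 1]), max(poly[, 2]))
  bbAreaMm2 <- (bb[3] - bb[1]) * (bb[4] - bb[2]) / 1e6
  pts <- .withSeed(seed, {
    lambda <- densityPerMm2 * relMax * bbAreaMm2
    n <- if (lambda > 0) stats::rpois(1, lambda) else 0L
    if (n == 0L) {
      matrix(numeric(0), 0, 2)
    } else {
      cand <- cbind(stats::runif(n, bb[1], bb[3]),
                    stats::runif(n, bb[2], bb[4]))
      keep <- .pointsInPolygon(cand, poly)
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand) > 0 && dvGradientSlope != 0) {
        u <- stats::runif(nrow(cand))
        cand <- cand[u < dens(.projectOnAxis(cand, dvAxis)) / relMax, ,
                     drop = FALSE]
      }
      cand
    }
  })
  PointPattern(pts, marker = marker, region = poly)
}
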