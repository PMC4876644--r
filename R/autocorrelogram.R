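# Two-dimensional spatial autocorrelogram: at each spatial lag the Pearson
# product-moment correlation between the image and its shifted copy, computed
# over exactly the overlapping mask-valid pixels,
#
#   r(tx,ty) = [ n*S(f g) - S(f) S(g) ] /
#              sqrt( [n*S(f^2) - S(f)^2] [n*S(g^2) - S(g)^2] ),
#
# with g the shifted image and all sums over the overlap. The six per-lag
# sums (n, S(f), S(g), S(f g), S(f^2), S(g^2)) are cross-correlations of the
# mask, the masked image and its square, evaluated for all lags at once via
# zero-padded FFTs. Lags with n below the minimum overlap, or with zero
# variance in either window, are carried as missing, never zero-filled.

# Cross-correlation C(ty,tx) = sum_xy A[y,x] * B[y-ty, x-tx] for
# |ty|,|tx| <= maxLag, returned as a (2*maxLag+1)^2 matrix, lag -maxLag
# first. Zero padding to >= dim + maxLag prevents circular wrap.
.xcorrLags <- function(A, B, maxLag) {
  d <- dim(A)
  P1 <- stats::nextn(d[1] + maxLag, c(2, 3))
  P2 <- stats::nextn(d[2] + maxLag, c(2, 3))
  Ap <- matrix(0, P1, P2); Ap[seq_len(d[1]), seq_len(d[2])] <- A
  Bp <- matrix(0, P1, P2); Bp[seq_len(d[1]), seq_len(d[2])] <- B
  CC <- Re(stats::fft(stats::fft(Ap) * Conj(stats::fft(Bp)),
                      inverse = TRUE)) / (P1 * P2)
  i1 <- c((P1 - maxLag + 1):P1, 1:(maxLag + 1))
  i2 <- c((P2 - maxLag + 1):P2, 1:(maxLag + 1))
  CC[i1, i2]
}

.rot180 <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]

#' Compute the 2D spatial autocorrelogram of an image
#'
#' For each lag `(tauX, tauY)` in `[-maxLag, maxLag]^2`, computes the Pearson
#' product-moment correlation between the unsmoothed image and its shifted
#' copy over exactly the overlapping (and mask-valid) pixels. Lags whose
#' overlap count `n` falls below `minOverlap`, or whose windows have zero
#' variance (e.g. blank regions), are flagged invalid and carried as `NA` --
#' the correlation is not estimated there. The result is point-symmetric,
#' `r(tau) = r(-tau)`, and `r(0, 0) = 1` for any non-constant image.
#'
#' @param img an [Image2D-class]; must be non-constant over valid pixels.
#' @param maxLag maximum lag in pixels; must be smaller than both image
#'   dimensions. Defaults to half the smaller dimension.
#' @param minOverlap minimum number of overlapping valid pixels for a lag to
#'   be estimated (default 20).
#' @return An [Autocorrelogram-class].
#' @examples
#' img <- genHexPatchImage(128, 128, seed = 1)
#' ac <- spatialAutocorrelogram(img, maxLag = 50)
#' corrMap(ac)[51, 51]  # r(0, 0) == 1
#' @seealso [gridScore()], [spatialCrossCorrelation()]
#' @export
spatialAutocorrelogram <- function(img, maxLag = NULL, minOverlap = 20L) {
  stopifnot(is(img, "Image2D"))
  d <- dim(img@pixels)
  if (is.null(maxLag)) maxLag <- floor(min(d) / 2)
  maxLag <- as.integer(maxLag)
  if (maxLag < 1L || maxLag >= min(d)) {
    stop("parameter error: maxLag must satisfy 1 <= maxLag < min(dim)")
  }
  minOverlap <- as.integer(minOverlap)
  v <- img@pixels[img@mask]
  if (length(v) < 2L || !(stats::sd(v) > 0)) {
    stop("degenerate input: image is constant over its valid pixels")
  }
  M <- img@mask * 1
  F1 <- img@pixels * M
  F2 <- F1 * F1
  n <- round(.xcorrLags(M, M, maxLag))
  Sf <- .xcorrLags(F1, M, maxLag)
  Sg <- .xcorrLags(M, F1, maxLag)
  Sfg <- .xcorrLags(F1, F1, maxLag)
  Sff <- .xcorrLags(F2, M, maxLag)
  Sgg <- .xcorrLags(M, F2, maxLag)
  num <- n * Sfg - Sf * Sg
  v1 <- n * Sff - Sf^2
  v2 <- n * Sgg - Sg^2
  # variance floor: FFT round-off scale for an exactly constant window
  floorTol <- 1e-6 * (n + 1) * max(abs(F1))^2
  valid <- n >= minOverlap & v1 > floorTol & v2 > floorTol
  r <- matrix(NA_real_, nrow(n), ncol(n))
  r[valid] <- num[valid] / sqrt(v1[valid] * v2[valid])
  r[valid] <- pmin(pmax(r[valid], -1), 1)
  # enforce exact point symmetry (true analytically; FFT noise otherwise)
  valid <- valid & .rot180(valid)
  rS <- (r + .rot180(r)) / 2
  r[valid] <- rS[valid]
  r[!valid] <- NA_real_
  new("Autocorrelogram", r = r, n = n, valid = valid, maxLag = maxLag,
      minOverlap = minOverlap, sourceShape = as.integer(d))
}

#' Write an autocorrelogram as TIFF maps
#'
#' Writes the correlation map as a 32-bit float TIFF with values packed by
#' the affine map `(r + 1) / 2` (so [-1, 1] maps onto [0, 1]; invalid lags
#' are written as 0 and distinguished by the mask) and the validity mask as
#' an 8-bit TIFF alongside it. The packing is recorded in a YAML sidecar.
#'
#' @param acorr an [Autocorrelogram-class].
#' @param prefix output path prefix; writes `<prefix>_r.tif`,
#'   `<prefix>_valid.tif` and `<prefix>_r.tif.yaml`.
#' @return The two TIFF paths, invisibly.
#' @export
writeAutocorrelogram <- function(acorr, prefix) {
  stopifnot(is(acorr, "Autocorrelogram"))
  rPath <- paste0(prefix, "_r.tif")
  vPath <- paste0(prefix, "_valid.tif")
  r <- (acorr@r + 1) / 2
  r[!acorr@valid] <- 0
  tiff::writeTIFF(r, rPath, bits.per.sample = 32L, reduce = FALSE)
  tiff::writeTIFF(acorr@valid * 1, vPath, bits.per.sample = 8L)
  yaml::write_yaml(list(packing = "r = 2 * stored - 1",
                        max_lag_px = acorr@maxLag,
                        min_overlap = acorr@minOverlap),
                   .sidecarPath(rPath))
  invisible(c(rPath, vPath))
}
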