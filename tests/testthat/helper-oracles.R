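# Independent oracles used against the package implementations.

# Naive double-loop per-lag Pearson autocorrelogram, straight from the
# product-moment sums; independent of the FFT path.
naiveAcorr <- function(px, mask = NULL, maxLag, minOverlap = 20) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(px), ncol(px))
  H <- nrow(px); W <- ncol(px)
  side <- 2L * maxLag + 1L
  r <- matrix(NA_real_, side, side)
  n <- matrix(0, side, side)
  for (ty in -maxLag:maxLag) {
    for (tx in -maxLag:maxLag) {
      ys <- max(1, 1 + ty):min(H, H + ty)
      xs <- max(1, 1 + tx):min(W, W + tx)
      f <- px[ys, xs, drop = FALSE]
      g <- px[ys - ty, xs - tx, drop = FALSE]
      ok <- mask[ys, xs, drop = FALSE] & mask[ys - ty, xs - tx, drop = FALSE]
      fv <- f[ok]; gv <- g[ok]
      nn <- length(fv)
      n[ty + maxLag + 1, tx + maxLag + 1] <- nn
      if (nn >= minOverlap) {
        num <- nn * sum(fv * gv) - sum(fv) * sum(gv)
        v1 <- nn * sum(fv^2) - sum(fv)^2
        v2 <- nn * sum(gv^2) - sum(gv)^2
        if (v1 > 1e-12 && v2 > 1e-12) {
          r[ty + maxLag + 1, tx + maxLag + 1] <- num / sqrt(v1 * v2)
        }
      }
    }
  }
  list(r = r, n = n)
}

# Exact two-tailed Mann-Whitney p by full enumeration of group assignments.
mwPermutationP <- function(a, b) {
  pool <- c(a, b)
  na <- length(a); N <- length(pool)
  rk <- rank(pool)
  uOf <- function(ix) sum(rk[ix]) - na * (na + 1) / 2
  combs <- utils::combn(N, na)
  Us <- apply(combs, 2, uOf)
  uObs <- uOf(seq_len(na))
  min(1, 2 * min(mean(Us <= uObs), mean(Us >= uObs)))
}

# Intensity-weighted blob centroids from a clean (noise-free) bump image:
# connected components above `thr`, centroid weighted by intensity. Blobs
# clipped by the frame are biased; callers use interior blobs only.
blobCentroids <- function(px, thr = 0.5) {
  lab <- EBImage::bwlabel(px > thr)
  idx <- which(lab > 0, arr.ind = TRUE)
  w <- px[lab > 0]
  l <- lab[lab > 0]
  cx <- tapply(w * (idx[, 2] - 1), l, sum) / tapply(w, l, sum)
  cy <- tapply(w * (idx[, 1] - 1), l, sum) / tapply(w, l, sum)
  cbind(x = as.numeric(cx), y = as.numeric(cy))  # 0-based pixel coords
}

hexTestImage <- function(seed = 1, widthPx = 256, heightPx = 256,
                         jitterUm = 0, noiseSd = 0) {
  genHexPatchImage(widthPx, heightPx, pixelSizeUm = 2, latticeSpacingUm = 80,
                   patchSigmaUm = 12, positionJitterUm = jitterUm,
                   backgroundNoiseSd = noiseSd, seed = seed)
}
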