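# Whole-image spatial cross-correlation: the Pearson product-moment
# correlation between two same-size monochrome channels over all jointly
# valid pixels, without smoothing -- the colocalization statistic. The
# dorsal/ventral paired design computes it per region and propagates the
# pairing key for downstream group summaries.

#' Whole-image Pearson spatial cross-correlation
#'
#' Computes the Pearson product-moment correlation between two same-size
#' single-channel images over all jointly mask-valid pixels, unsmoothed. The
#' coefficient varies from -1 (anti-correlated) through 0 (uncorrelated) to
#' 1 (correlated) and is invariant to uniform linear brightness/contrast
#' adjustment with positive gain of either channel.
#'
#' @param img1,img2 [Image2D-class] objects of identical shape, both
#'   non-constant over the jointly valid pixels.
#' @param roiLabel region label carried on the result.
#' @param pairId pairing key carried on the result.
#' @param markerPair character(2), names of the two channels.
#' @param paired logical flag carried on the result.
#' @return A [CrossCorrResult-class].
#' @examples
#' base <- genHexPatchImage(128, 128, seed = 1)
#' corrCoef(spatialCrossCorrelation(base, base))  # 1
#' @export
spatialCrossCorrelation <- function(img1, img2, roiLabel = "whole",
                                    pairId = NA_character_,
                                    markerPair = c("ch1", "ch2"),
                                    paired = NA) {
  stopifnot(is(img1, "Image2D"), is(img2, "Image2D"))
  if (!identical(dim(img1@pixels), dim(img2@pixels))) {
    stop("geometry error: images must have identical shapes")
  }
  ok <- img1@mask & img2@mask
  n <- sum(ok)
  if (n < 2L) stop("degenerate input: fewer than 2 jointly valid pixels")
  x <- img1@pixels[ok]
  y <- img2@pixels[ok]
  if (!(stats::sd(x) > 0) || !(stats::sd(y) > 0)) {
    stop("degenerate input: a channel is constant over the jointly valid pixels")
  }
  r <- min(max(stats::cor(x, y), -1), 1)
  new("CrossCorrResult", r = r, nPixels = as.integer(n),
      roiLabel = roiLabel, pairId = as.character(pairId),
      paired = if (is.na(paired)) !is.na(pairId) else paired,
      markerPair = markerPair)
}

#' Dorsal/ventral paired cross-correlation design
#'
#' Computes one cross-correlation per ROI from a two-channel section. ROIs
#' labelled dorsal and ventral sharing a `pairId` form a pair and must have
#' identical crop sizes; an ROI whose partner is missing (e.g. section
#' damage) is accepted and flagged unpaired.
#'
#' @param ch1,ch2 [Image2D-class] channels of identical shape.
#' @param rois list of [ROI-class] regions with labels and pairing keys.
#' @param markerPair character(2), channel names.
#' @return A list of [CrossCorrResult-class], one per ROI, in input order.
#' @seealso [crossCorrTable()], [dvSummary()]
#' @export
pairedDvCrossCorrelation <- function(ch1, ch2, rois,
                                     markerPair = c("ch1", "ch2")) {
  stopifnot(is(ch1, "Image2D"), is(ch2, "Image2D"))
  pids <- vapply(rois, function(r) r@pairId, character(1))
  labs <- vapply(rois, function(r) r@label, character(1))
  paired <- vapply(seq_along(rois), function(i) {
    !is.na(pids[i]) && sum(pids == pids[i], na.rm = TRUE) >= 2L
  }, logical(1))
  # paired regions must crop to identical sizes
  for (pid in unique(pids[paired])) {
    members <- which(pids == pid)
    sizes <- lapply(rois[members], function(r) {
      bb <- .roiBoundingBox(r)
      c(bb[3] - bb[1], bb[4] - bb[2])
    })
    if (length(unique(vapply(sizes, paste, character(1), collapse = "x"))) > 1L) {
      stop("geometry error: paired ROIs (pair '", pid,
           "') must have identical sizes")
    }
  }
  lapply(seq_along(rois), function(i) {
    spatialCrossCorrelation(extractRoi(ch1, rois[[i]]),
                            extractRoi(ch2, rois[[i]]),
                            roiLabel = labs[i], pairId = pids[i],
                            markerPair = markerPair, paired = paired[i])
  })
}

#' Tabulate cross-correlation results
#'
#' @param results list of [CrossCorrResult-class].
#' @return data.frame with columns `roi_label`, `pair_id`, `paired`, `r`,
#'   `n_pixels`, `marker_pair`.
#' @export
crossCorrTable <- function(results) {
  do.call(rbind, lapply(results, function(x) {
    data.frame(roi_label = x@roiLabel, pair_id = x@pairId,
               paired = x@paired, r = x@r, n_pixels = x@nPixels,
               marker_pair = paste(x@markerPair, collapse = ":"),
               stringsAsFactors = FALSE)
  }))
}

#' Group summary of cross-correlations by region label
#'
#' Mean and standard deviation of the Pearson coefficient per anatomical
#' label, as reported for dorsal/ventral colocalization comparisons.
#'
#' @param tab data.frame from [crossCorrTable()].
#' @return data.frame with columns `roi_label`, `n`, `mean_r`, `sd_r`.
#' @export
dvSummary <- function(tab) {
  out <- do.call(rbind, lapply(split(tab, tab$roi_label), function(g) {
    data.frame(roi_label = g$roi_label[1], n = nrow(g),
               mean_r = mean(g$r),
               sd_r = if (nrow(g) > 1) stats::sd(g$r) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
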