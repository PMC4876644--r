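# Laminar width morphometry on parasagittal sections: at each named sample
# position (dorsal, medial, ventral) a ray is cast along the local normal to
# the pia, and each layer's width is the distance between its two bounding
# polylines along that ray. Widths therefore sum exactly to the
# pia-to-white-matter distance at every position.

#' Layer widths at the profile's sample positions
#'
#' For each sample position, measures the width of each layer as the
#' distance between consecutive boundary polylines along the local normal to
#' the pia, plus proportional widths (layer / total). Boundaries must be
#' encountered in their stored order along each ray; a ray that meets them
#' out of order (crossing boundaries) or misses one raises a geometry error.
#'
#' @param profile a [LayerProfile-class].
#' @return data.frame with columns `position`, `layer`, `width_um`,
#'   `proportion`, `total_um`. Layers are named after the boundaries that
#'   delimit them (`"pia-L1/2"` etc. for unnamed conventions, or the names
#'   supplied on the profile).
#' @examples
#' x <- seq(0, 2000, by = 100)
#' prof <- layerProfile(list(
#'   pia = cbind(x, 0), `L2/3` = cbind(x, 100),
#'   `L3/4` = cbind(x, 343), wm = cbind(x, 995)))
#' layerWidths(prof)
#' @export
layerWidths <- function(profile) {
  stopifnot(is(profile, "LayerProfile"))
  bnd <- profile@boundaries
  nb <- length(bnd)
  layerNames <- paste(names(bnd)[-nb], names(bnd)[-1], sep = "-")
  pia <- bnd[[1]]
  out <- list()
  for (p in seq_along(profile@samplePositions)) {
    posName <- names(profile@samplePositions)[p]
    pt <- .polylinePointTangent(pia, profile@samplePositions[p])
    nrm <- c(-pt$tangent[2], pt$tangent[1])
    # orient the normal towards the deepest boundary
    uLast <- .rayPolylineU(pt$point, nrm, bnd[[nb]])
    if (is.na(uLast)) {
      nrm <- -nrm
      uLast <- .rayPolylineU(pt$point, nrm, bnd[[nb]])
    }
    if (is.na(uLast)) {
      stop("geometry error: normal at position '", posName,
           "' does not reach the deepest boundary")
    }
    u <- c(0, vapply(2:nb, function(k) {
      .rayPolylineU(pt$point, nrm, bnd[[k]])
    }, numeric(1)))
    if (anyNA(u)) {
      stop("geometry error: normal at position '", posName,
           "' misses a boundary")
    }
    if (any(diff(u) <= 0)) {
      stop("geometry error: boundaries crossed along the normal at ",
           "position '", posName, "'")
    }
    w <- diff(u)
    out[[p]] <- data.frame(position = posName, layer = layerNames,
                           width_um = w, proportion = w / u[nb],
                           total_um = u[nb], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
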