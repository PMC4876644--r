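#' @import methods
NULL

#' Single-channel intensity image with pixel size
#'
#' Container for one monochrome channel of a histological section: a numeric
#' matrix of intensities (arbitrary units), the pixel size in micrometres per
#' pixel, and a logical validity mask of identical shape. Rows index the image
#' y (vertical) direction and columns the x (horizontal) direction, origin at
#' the top-left pixel; anatomical orientation is never inferred from the image
#' and is carried only by the dorsoventral axis of an [ROI-class].
#'
#' @slot pixels numeric matrix of finite intensities.
#' @slot pixelSizeUm single positive number, micrometres per pixel.
#' @slot mask logical matrix, same shape as `pixels`; `FALSE` marks pixels
#'   that must not enter any statistic (e.g. outside a polygon ROI).
#' @slot meta list of provenance entries (generator settings, linear
#'   adjustments applied, source file).
#'
#' @seealso [Image2D()], [spatialAutocorrelogram()], [spatialCrossCorrelation()]
#' @exportClass Image2D
setClass("Image2D",
  slots = c(
    pixels = "matrix",
    pixelSizeUm = "numeric",
    mask = "matrix",
    meta = "list"
  )
)

setValidity("Image2D", function(object) {
  msg <- character(0)
  if (!is.numeric(object@pixels)) {
    msg <- c(msg, "pixels must be a numeric matrix")
  } else if (!all(is.finite(object@pixels))) {
    msg <- c(msg, "all pixel intensities must be finite")
  }
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0) {
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  }
  if (!is.logical(object@mask)) {
    msg <- c(msg, "mask must be a logical matrix")
  } else if (!identical(dim(object@mask), dim(object@pixels))) {
    msg <- c(msg, "mask must have the same shape as pixels")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an Image2D
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param pixelSizeUm pixel size in micrometres per pixel (> 0).
#' @param mask optional logical matrix marking valid pixels; defaults to all
#'   valid.
#' @param meta optional list of provenance entries.
#' @return An [Image2D-class] object.
#' @examples
#' img <- Image2D(matrix(runif(64), 8, 8), pixelSizeUm = 2)
#' dim(img)
#' @export
Image2D <- function(pixels, pixelSizeUm, mask = NULL, meta = list()) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  }
  new("Image2D", pixels = pixels, pixelSizeUm = as.numeric(pixelSizeUm),
      mask = mask, meta = meta)
}

#' @describeIn Image2D image dimensions (rows, columns).
#' @param x an `Image2D`.
#' @export
setMethod("dim", "Image2D", function(x) dim(x@pixels))

setMethod("show", "Image2D", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Image2D: %d x %d px @ %.4g um/px\n", d[1], d[2],
              object@pixelSizeUm))
  cat(sprintf("  intensity range: [%.4g, %.4g]; valid pixels: %d/%d\n",
              min(object@pixels), max(object@pixels),
              sum(object@mask), length(object@mask)))
})

#' Region of interest with a declared dorsoventral axis
#'
#' A rectangle or simple polygon in pixel coordinates, together with the unit
#' vector pointing dorsal-to-ventral in image coordinates, an anatomical
#' label, and an optional pairing key linking the dorsal and ventral regions
#' taken from one section. Pixel coordinates are 0-based; rectangles are
#' half-open `[x0, x1) x [y0, y1)` so that paired crops of equal nominal size
#' have identical pixel dimensions.
#'
#' @slot kind `"rect"` or `"polygon"`.
#' @slot coords for a rectangle, `c(x0, y0, x1, y1)`; for a polygon, a
#'   k x 2 matrix of vertices (columns x, y).
#' @slot dvAxis unit vector (x, y) pointing dorsal to ventral.
#' @slot label one of `"dorsal"`, `"ventral"`, `"intermediate"`, `"whole"`.
#' @slot pairId character key linking a dorsal/ventral pair, or `NA`.
#'
#' @seealso [rectROI()], [polygonROI()], [extractRoi()]
#' @exportClass ROI
setClass("ROI",
  slots = c(
    kind = "character",
    coords = "numeric",
    vertices = "matrix",
    dvAxis = "numeric",
    label = "character",
    pairId = "character"
  ),
  prototype = prototype(vertices = matrix(numeric(0), 0, 2),
                        coords = numeric(0))
)

setValidity("ROI", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("rect", "polygon")) {
    msg <- c(msg, "kind must be 'rect' or 'polygon'")
  }
  if (object@kind == "rect") {
    if (length(object@coords) != 4L ||
        object@coords[3] <= object@coords[1] ||
        object@coords[4] <= object@coords[2]) {
      msg <- c(msg, "rect coords must be c(x0, y0, x1, y1) with x1 > x0, y1 > y0")
    }
  } else if (nrow(object@vertices) < 3L) {
    msg <- c(msg, "polygon needs at least 3 vertices")
  }
  if (length(object@dvAxis) != 2L ||
      abs(sqrt(sum(object@dvAxis^2)) - 1) > 1e-6) {
    msg <- c(msg, "dvAxis must be a unit-length 2-vector")
  }
  if (!object@label %in% c("dorsal", "ventral", "intermediate", "whole")) {
    msg <- c(msg, "label must be dorsal/ventral/intermediate/whole")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a rectangular ROI
#'
#' @param x0,y0,x1,y1 half-open pixel bounds `[x0, x1) x [y0, y1)`, 0-based.
#' @param dvAxis vector pointing dorsal to ventral in image coordinates;
#'   normalized internally.
#' @param label anatomical label (`"dorsal"`, `"ventral"`, `"intermediate"`,
#'   `"whole"`).
#' @param pairId optional key linking a dorsal/ventral pair from one section.
#' @return An [ROI-class] object.
#' @examples
#' roi <- rectROI(0, 0, 128, 256, dvAxis = c(0, 1), label = "dorsal", pairId = "s1")
#' @export
rectROI <- function(x0, y0, x1, y1, dvAxis = c(0, 1), label = "whole",
                    pairId = NA_character_) {
  dvAxis <- as.numeric(dvAxis)
  dvAxis <- dvAxis / sqrt(sum(dvAxis^2))
  new("ROI", kind = "rect", coords = as.numeric(c(x0, y0, x1, y1)),
      dvAxis = dvAxis, label = label, pairId = as.character(pairId))
}

#' Construct a polygonal ROI
#'
#' @param vertices k x 2 matrix of polygon vertices in pixel coordinates
#'   (columns x, y); the polygon must be simple (non-self-intersecting).
#' @inheritParams rectROI
#' @return An [ROI-class] object.
#' @export
polygonROI <- function(vertices, dvAxis = c(0, 1), label = "whole",
                       pairId = NA_character_) {
  vertices <- as.matrix(vertices)
  if (!.polyIsSimple(vertices)) {
    stop("geometry error: polygon is self-intersecting")
  }
  dvAxis <- as.numeric(dvAxis)
  dvAxis <- dvAxis / sqrt(sum(dvAxis^2))
  new("ROI", kind = "polygon", vertices = vertices, dvAxis = dvAxis,
      label = label, pairId = as.character(pairId))
}

setMethod("show", "ROI", function(object) {
  if (object@kind == "rect") {
    cat(sprintf("ROI (rect [%g,%g) x [%g,%g)) label=%s pair=%s\n",
                object@coords[1], object@coords[3], object@coords[2],
                object@coords[4], object@label, object@pairId))
  } else {
    cat(sprintf("ROI (polygon, %d vertices) label=%s pair=%s\n",
                nrow(object@vertices), object@label, object@pairId))
  }
})

#' Two-dimensional spatial autocorrelogram
#'
#' Map of Pearson product-moment correlations between an image and its
#' spatially shifted copy, indexed by lag (tau_x, tau_y) over
#' `[-maxLag, maxLag]^2`. Each lag's correlation is computed over exactly the
#' overlapping, mask-valid pixels; lags whose overlap count falls below
#' `minOverlap` or whose windows have zero variance are flagged invalid (`NA`
#' in `r`), never zero-filled.
#'
#' Matrix element `[a, b]` holds the lag `tau_y = a - maxLag - 1` (row shift),
#' `tau_x = b - maxLag - 1` (column shift).
#'
#' @slot r numeric matrix of correlations, `NA` where invalid.
#' @slot n numeric matrix of overlapping valid-pixel counts per lag.
#' @slot valid logical matrix; `TRUE` where the correlation is defined.
#' @slot maxLag integer, maximum lag in pixels.
#' @slot minOverlap integer, minimum overlap count for a lag to be estimated.
#' @slot sourceShape integer(2), shape of the source image.
#'
#' @seealso [spatialAutocorrelogram()], [gridScore()]
#' @exportClass Autocorrelogram
setClass("Autocorrelogram",
  slots = c(
    r = "matrix",
    n = "matrix",
    valid = "matrix",
    maxLag = "integer",
    minOverlap = "integer",
    sourceShape = "integer"
  )
)

setValidity("Autocorrelogram", function(object) {
  msg <- character(0)
  side <- 2L * object@maxLag + 1L
  if (!identical(dim(object@r), c(side, side))) {
    msg <- c(msg, "r must be a (2*maxLag+1) square matrix")
  }
  if (!identical(dim(object@n), dim(object@r)) ||
      !identical(dim(object@valid), dim(object@r))) {
    msg <- c(msg, "n and valid must match the shape of r")
  }
  rv <- object@r[object@valid]
  if (length(rv) && any(abs(rv) > 1 + 1e-9)) {
    msg <- c(msg, "valid correlations must lie in [-1, 1]")
  }
  if (any(object@valid & object@n < object@minOverlap)) {
    msg <- c(msg, "lags with n < minOverlap must be invalid")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "Autocorrelogram", function(object) {
  cat(sprintf("Autocorrelogram: lags [-%d, %d]^2 from a %d x %d image\n",
              object@maxLag, object@maxLag, object@sourceShape[1],
              object@sourceShape[2]))
  cat(sprintf("  valid lags: %d/%d (min overlap %d)\n", sum(object@valid),
              length(object@valid), object@minOverlap))
})

#' Rotational grid score of an autocorrelogram
#'
#' The grid score measures six-fold (hexagonal) rotational symmetry: an
#' annulus containing the six inner peaks of the autocorrelogram is
#' correlated with itself rotated by 30, 60, 90, 120 and 150 degrees, and the
#' score is `min(r60, r120) - max(r30, r90, r150)`. It ranges over [-2, 2];
#' positive values indicate hexagonal periodicity. When fewer than six
#' off-center peaks are detectable the result is flagged non-periodic and the
#' score is `NA`, never a sentinel number.
#'
#' @slot score numeric, the grid score (`NA` when flagged non-periodic).
#' @slot periodic logical; `FALSE` when no six-peak ring was found.
#' @slot annulusInnerPx,annulusOuterPx annulus radii in pixels.
#' @slot rotCorr named numeric, annulus correlations at the five rotations.
#' @slot peakSpacingPx median radial distance of the six inner peaks.
#' @slot peaks matrix of detected peak lags (columns tauX, tauY, r, radius).
#' @slot reason character; why a result was flagged non-periodic.
#'
#' @seealso [gridScore()]
#' @exportClass GridScoreResult
setClass("GridScoreResult",
  slots = c(
    score = "numeric",
    periodic = "logical",
    annulusInnerPx = "numeric",
    annulusOuterPx = "numeric",
    rotCorr = "numeric",
    peakSpacingPx = "numeric",
    peaks = "matrix",
    reason = "character"
  )
)

setValidity("GridScoreResult", function(object) {
  if (object@periodic && (!is.finite(object@score) ||
      object@score < -2 - 1e-9 || object@score > 2 + 1e-9)) {
    return("score must lie in [-2, 2]")
  }
  if (object@periodic &&
      !(object@annulusInnerPx > 0 &&
        object@annulusInnerPx < object@annulusOuterPx)) {
    return("annulus radii must satisfy 0 < inner < outer")
  }
  TRUE
})

setMethod("show", "GridScoreResult", function(object) {
  if (object@periodic) {
    cat(sprintf("GridScoreResult: score %.3f (annulus %.1f-%.1f px, ring %.1f px)\n",
                object@score, object@annulusInnerPx, object@annulusOuterPx,
                object@peakSpacingPx))
    cat("  rotations: ",
        paste(sprintf("%s=%.3f", names(object@rotCorr), object@rotCorr),
              collapse = " "), "\n")
  } else {
    cat(sprintf("GridScoreResult: no periodicity (%s); score undefined\n",
                object@reason))
  }
})

#' Whole-image Pearson spatial cross-correlation result
#'
#' The colocalization statistic between two same-size marker channels: the
#' Pearson product-moment correlation over all jointly valid pixels, without
#' smoothing. Carries the anatomical label and pairing key of the region it
#' was computed on so dorsal/ventral paired designs can be summarized
#' downstream.
#'
#' @slot r Pearson correlation in [-1, 1].
#' @slot nPixels number of pixels entering the sums (>= 2).
#' @slot roiLabel region label (`"dorsal"`, `"ventral"`, `"whole"`, ...).
#' @slot pairId pairing key, `NA` when unpaired.
#' @slot paired logical; `FALSE` flags an unpaired region.
#' @slot markerPair names of the two channels.
#'
#' @seealso [spatialCrossCorrelation()], [pairedDvCrossCorrelation()]
#' @exportClass CrossCorrResult
setClass("CrossCorrResult",
  slots = c(
    r = "numeric",
    nPixels = "integer",
    roiLabel = "character",
    pairId = "character",
    paired = "logical",
    markerPair = "character"
  )
)

setValidity("CrossCorrResult", function(object) {
  msg <- character(0)
  if (abs(object@r) > 1 + 1e-9) msg <- c(msg, "r must lie in [-1, 1]")
  if (object@nPixels < 2L) msg <- c(msg, "nPixels must be >= 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CrossCorrResult", function(object) {
  cat(sprintf("CrossCorrResult: r = %.4f (n = %d px) %s/%s label=%s pair=%s%s\n",
              object@r, object@nPixels, object@markerPair[1],
              object@markerPair[2], object@roiLabel, object@pairId,
              if (object@paired) "" else " [unpaired]"))
})

#' Annotated cell positions within a region polygon
#'
#' Point pattern of annotated cell coordinates (micrometres) for one marker,
#' together with the simple polygon bounding the counting region and its
#' area in square millimetres. The stored area always equals the polygon's
#' shoelace area (checked to 0.1 percent), so densities are exactly
#' count / area.
#'
#' @slot points n x 2 matrix of cell coordinates (columns x_um, y_um).
#' @slot marker marker name (e.g. `"calbindin"`).
#' @slot region k x 2 matrix of polygon vertices in micrometres.
#' @slot regionAreaMm2 polygon area in mm^2 (> 0).
#'
#' @seealso [PointPattern()], [cellDensity()], [dvPartition()]
#' @exportClass PointPattern
setClass("PointPattern",
  slots = c(
    points = "matrix",
    marker = "character",
    region = "matrix",
    regionAreaMm2 = "numeric"
  )
)

setValidity("PointPattern", function(object) {
  msg <- character(0)
  if (ncol(object@points) != 2L) {
    msg <- c(msg, "points must be an n x 2 matrix (x_um, y_um)")
  }
  if (nrow(object@region) < 3L) {
    msg <- c(msg, "region polygon needs at least 3 vertices")
  } else {
    area <- .polyArea(object@region) / 1e6
    if (!(object@regionAreaMm2 > 0)) {
      msg <- c(msg, "regionAreaMm2 must be positive")
    } else if (abs(area - object@regionAreaMm2) > 1e-3 * object@regionAreaMm2) {
      msg <- c(msg, "regionAreaMm2 must equal the polygon area within 0.1%")
    }
    if (nrow(object@points) > 0) {
      inside <- .pointsInPolygon(object@points, object@region,
                                 boundaryTolUm = 1e-6)
      if (!all(inside)) {
        msg <- c(msg, "all points must lie inside the region polygon")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PointPattern
#'
#' @param points n x 2 matrix or data.frame of cell coordinates in
#'   micrometres (columns x_um, y_um).
#' @param marker marker name.
#' @param region k x 2 matrix of simple-polygon vertices in micrometres.
#' @return A [PointPattern-class]; the region area is computed by the
#'   shoelace formula.
#' @examples
#' sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
#' pp <- PointPattern(cbind(runif(50, 0, 1000), runif(50, 0, 1000)),
#'                    marker = "calbindin", region = sq)
#' cellDensity(pp)
#' @export
PointPattern <- function(points, marker, region) {
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), 0, 2)
  colnames(points) <- c("x_um", "y_um")
  region <- as.matrix(region)
  if (!.polyIsSimple(region)) {
    stop("geometry error: region polygon is self-intersecting")
  }
  new("PointPattern", points = points, marker = marker, region = region,
      regionAreaMm2 = .polyArea(region) / 1e6)
}

setMethod("show", "PointPattern", function(object) {
  cat(sprintf("PointPattern: %d '%s' cells in %.4g mm^2 (%.1f cells/mm^2)\n",
              nrow(object@points), object@marker, object@regionAreaMm2,
              nrow(object@points) / object@regionAreaMm2))
})

#' @describeIn PointPattern number of cells in the pattern.
#' @param x a `PointPattern`.
#' @export
setMethod("length", "PointPattern", function(x) nrow(x@points))

#' Laminar boundary profile of a parasagittal section
#'
#' Ordered boundary polylines (pia first, white matter last) in micrometres,
#' plus named sample positions expressed as arc-length fractions along the
#' pia where widths are read. Layer widths are measured along the local
#' normal to the pia at each sample position.
#'
#' @slot boundaries named list of k x 2 matrices (x_um, y_um), ordered from
#'   the pia to the white matter.
#' @slot samplePositions named numeric vector of arc-length fractions in
#'   [0, 1] along the pia (conventionally dorsal, medial, ventral).
#'
#' @seealso [layerProfile()], [layerWidths()]
#' @exportClass LayerProfile
setClass("LayerProfile",
  slots = c(
    boundaries = "list",
    samplePositions = "numeric"
  )
)

setValidity("LayerProfile", function(object) {
  msg <- character(0)
  if (length(object@boundaries) < 2L) {
    msg <- c(msg, "need at least two boundaries (pia and white matter)")
  }
  if (is.null(names(object@boundaries)) ||
      anyNA(names(object@boundaries))) {
    msg <- c(msg, "boundaries must be named")
  }
  for (b in object@boundaries) {
    if (!is.matrix(b) || ncol(b) != 2L || nrow(b) < 2L) {
      msg <- c(msg, "each boundary must be a k x 2 matrix with k >= 2")
      break
    }
  }
  if (any(object@samplePositions < 0 | object@samplePositions > 1)) {
    msg <- c(msg, "samplePositions must be arc-length fractions in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LayerProfile
#'
#' @param boundaries named list of k x 2 matrices of boundary polylines in
#'   micrometres, ordered pia first, white matter last.
#' @param samplePositions named numeric vector of arc-length fractions along
#'   the pia at which widths are measured.
#' @return A [LayerProfile-class].
#' @export
layerProfile <- function(boundaries,
                         samplePositions = c(dorsal = 0.15, medial = 0.5,
                                             ventral = 0.85)) {
  boundaries <- lapply(boundaries, function(b) {
    b <- as.matrix(b)
    storage.mode(b) <- "double"
    b
  })
  new("LayerProfile", boundaries = boundaries,
      samplePositions = samplePositions)
}

setMethod("show", "LayerProfile", function(object) {
  cat(sprintf("LayerProfile: %d boundaries (%s), %d sample positions\n",
              length(object@boundaries),
              paste(names(object@boundaries), collapse = " > "),
              length(object@samplePositions)))
})
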