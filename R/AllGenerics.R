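#' Accessors for patchdev objects
#'
#' Accessor generics for the intensity matrix, pixel size and validity mask
#' of an [Image2D-class]; the correlation map, overlap counts and lag
#' validity of an [Autocorrelogram-class]; and the coordinates, marker,
#' region polygon and area of a [PointPattern-class].
#'
#' @param x the object.
#' @return The slot contents (matrix, numeric or character as documented on
#'   each class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "Image2D", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))
#' @rdname accessors
#' @export
setMethod("pixelSizeUm", "Image2D", function(x) x@pixelSizeUm)

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setMethod("validMask", "Image2D", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("corrMap", function(x) standardGeneric("corrMap"))
#' @rdname accessors
#' @export
setMethod("corrMap", "Autocorrelogram", function(x) x@r)

#' @rdname accessors
#' @export
setGeneric("lagCounts", function(x) standardGeneric("lagCounts"))
#' @rdname accessors
#' @export
setMethod("lagCounts", "Autocorrelogram", function(x) x@n)

#' @rdname accessors
#' @export
setGeneric("lagValid", function(x) standardGeneric("lagValid"))
#' @rdname accessors
#' @export
setMethod("lagValid", "Autocorrelogram", function(x) x@valid)

#' @rdname accessors
#' @export
setGeneric("maxLag", function(x) standardGeneric("maxLag"))
#' @rdname accessors
#' @export
setMethod("maxLag", "Autocorrelogram", function(x) x@maxLag)

#' @rdname accessors
#' @export
setGeneric("score", function(x) standardGeneric("score"))
#' @rdname accessors
#' @export
setMethod("score", "GridScoreResult", function(x) x@score)

#' @rdname accessors
#' @export
setGeneric("isPeriodic", function(x) standardGeneric("isPeriodic"))
#' @rdname accessors
#' @export
setMethod("isPeriodic", "GridScoreResult", function(x) x@periodic)

#' @rdname accessors
#' @export
setGeneric("rotationalCorrelations",
           function(x) standardGeneric("rotationalCorrelations"))
#' @rdname accessors
#' @export
setMethod("rotationalCorrelations", "GridScoreResult", function(x) x@rotCorr)

#' @rdname accessors
#' @export
setGeneric("peakSpacingPx", function(x) standardGeneric("peakSpacingPx"))
#' @rdname accessors
#' @export
setMethod("peakSpacingPx", "GridScoreResult", function(x) x@peakSpacingPx)

#' @rdname accessors
#' @export
setGeneric("corrCoef", function(x) standardGeneric("corrCoef"))
#' @rdname accessors
#' @export
setMethod("corrCoef", "CrossCorrResult", function(x) x@r)

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setMethod("coords", "PointPattern", function(x) x@points)

#' @rdname accessors
#' @export
setGeneric("marker", function(x) standardGeneric("marker"))
#' @rdname accessors
#' @export
setMethod("marker", "PointPattern", function(x) x@marker)

#' @rdname accessors
#' @export
setGeneric("regionPolygon", function(x) standardGeneric("regionPolygon"))
#' @rdname accessors
#' @export
setMethod("regionPolygon", "PointPattern", function(x) x@region)

#' @rdname accessors
#' @export
setGeneric("regionAreaMm2", function(x) standardGeneric("regionAreaMm2"))
#' @rdname accessors
#' @export
setMethod("regionAreaMm2", "PointPattern", function(x) x@regionAreaMm2)
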