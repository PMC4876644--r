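# Image, ROI and point-table I/O. Intensities are preserved exactly as
# stored: TIFFs are read as raw integer sample values, never rescaled or
# smoothed. Pixel size is explicit bookkeeping: it comes from the caller or
# from a YAML sidecar, never from guessed magnification.

.roiBoundingBox <- function(roi) {
  if (roi@kind == "rect") {
    roi@coords
  } else {
    v <- roi@vertices
    c(floor(min(v[, 1])), floor(min(v[, 2])),
      ceiling(max(v[, 1])), ceiling(max(v[, 2])))
  }
}

.sidecarPath <- function(path) paste0(path, ".yaml")

#' Read a single-channel image
#'
#' Reads an 8/16-bit single-channel TIFF or PNG. Intensities are preserved
#' exactly as stored (raw sample values; no smoothing, no rescaling). The
#' pixel size must be supplied explicitly or be present in a YAML sidecar
#' (`<path>.yaml`, key `pixel_size_um`) written by [writeImage()].
#'
#' @param path image file path (`.tif`, `.tiff` or `.png`).
#' @param pixelSizeUm pixel size in micrometres per pixel; `NULL` reads it
#'   from the sidecar.
#' @return An [Image2D-class].
#' @seealso [writeImage()]
#' @export
readImage <- function(path, pixelSizeUm = NULL) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    px <- png::readPNG(path)
    if (is.matrix(px)) {
      # readPNG normalizes by the bit-depth maximum; restore stored values
      denom <- if (max(abs(px * 255 - round(px * 255))) < 1e-9) 255 else 65535
      px <- round(px * denom)
    }
  } else {
    stop("format error: unsupported image format '", ext,
         "' (use single-channel TIFF or PNG)")
  }
  if (!is.matrix(px)) {
    stop("format error: multi-channel image; export each channel as a ",
         "separate single-channel file")
  }
  storage.mode(px) <- "double"
  meta <- list(source = path)
  if (is.null(pixelSizeUm)) {
    sc <- .sidecarPath(path)
    if (!file.exists(sc)) {
      stop("configuration error: pixel size missing; pass pixelSizeUm or ",
           "provide a sidecar ", sc)
    }
    side <- yaml::read_yaml(sc)
    if (is.null(side$pixel_size_um)) {
      stop("configuration error: sidecar ", sc, " lacks pixel_size_um")
    }
    pixelSizeUm <- side$pixel_size_um
    meta$sidecar <- side
  }
  Image2D(px, pixelSizeUm, meta = meta)
}

#' Write an image as 16-bit grayscale TIFF with a YAML sidecar
#'
#' Intensities must lie in [0, 1]; they are quantized to 16 bits as
#' `floor(x * 65535)`, a positive affine map that leaves all Pearson-based
#' statistics unchanged. The sidecar records the pixel size and the image's
#' provenance metadata (generator settings including the seed, adjustments).
#'
#' @param img an [Image2D-class] with intensities in [0, 1].
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
writeImage <- function(img, path) {
  stopifnot(is(img, "Image2D"))
  if (min(img@pixels) < 0 || max(img@pixels) > 1) {
    stop("input error: writeImage expects intensities in [0, 1]")
  }
  tiff::writeTIFF(img@pixels, path, bits.per.sample = 16L)
  yaml::write_yaml(c(list(pixel_size_um = img@pixelSizeUm), img@meta),
                   .sidecarPath(path))
  invisible(path)
}

#' Extract an ROI as a cropped image
#'
#' Rectangular ROIs crop the half-open pixel range `[x0, x1) x [y0, y1)`.
#' Polygonal ROIs crop the polygon's bounding box and mark outside-polygon
#' pixels invalid in the crop's mask (they enter no downstream statistic).
#' Paired dorsal/ventral rectangles of equal nominal size therefore always
#' produce crops of identical shape.
#'
#' @param img an [Image2D-class].
#' @param roi an [ROI-class] lying within the image bounds.
#' @return An [Image2D-class] crop.
#' @export
extractRoi <- function(img, roi) {
  stopifnot(is(img, "Image2D"), is(roi, "ROI"))
  d <- dim(img@pixels)
  bb <- .roiBoundingBox(roi)
  if (bb[1] < 0 || bb[2] < 0 || bb[3] > d[2] || bb[4] > d[1]) {
    stop("geometry error: ROI exceeds image bounds")
  }
  rows <- (bb[2] + 1):bb[4]
  cols <- (bb[1] + 1):bb[3]
  px <- img@pixels[rows, cols, drop = FALSE]
  mk <- img@mask[rows, cols, drop = FALSE]
  if (roi@kind == "polygon") {
    xs <- bb[1] + (seq_along(cols) - 0.5)
    ys <- bb[2] + (seq_along(rows) - 0.5)
    PX <- matrix(xs, length(rows), length(cols), byrow = TRUE)
    PY <- matrix(ys, length(rows), length(cols))
    inside <- matrix(.pointsInPolygon(cbind(as.vector(PX), as.vector(PY)),
                                      roi@vertices),
                     length(rows), length(cols))
    mk <- mk & inside
  }
  Image2D(px, img@pixelSizeUm, mask = mk,
          meta = c(img@meta, list(roi = list(label = roi@label,
                                             pair_id = roi@pairId,
                                             bbox = bb))))
}

#' Uniform linear brightness/contrast adjustment
#'
#' The only preprocessing permitted ahead of the correlation statistics:
#' `pixels <- gain * pixels + offset` applied uniformly. All Pearson-based
#' statistics are invariant to this map for `gain > 0`; a non-positive gain
#' would flip or destroy the correlation structure and is rejected.
#'
#' @param img an [Image2D-class].
#' @param gain multiplicative factor (> 0).
#' @param offset additive offset.
#' @return The adjusted [Image2D-class]; the adjustment is recorded in
#'   `meta$adjustments`.
#' @export
linearAdjust <- function(img, gain = 1, offset = 0) {
  stopifnot(is(img, "Image2D"))
  if (!(gain > 0)) {
    stop("parameter error: gain must be > 0 (a non-positive gain would ",
         "flip or destroy the correlation structure)")
  }
  meta <- img@meta
  meta$adjustments <- c(meta$adjustments,
                        list(list(gain = gain, offset = offset)))
  Image2D(gain * img@pixels + offset, img@pixelSizeUm, mask = img@mask,
          meta = meta)
}

#' Translate an ROI by whole pixels
#'
#' Convenience for moving an ROI into the frame of a cropped or generated
#' image (e.g. the bounding-box frame of [genDvGradientMask()]).
#'
#' @param roi an [ROI-class].
#' @param dx,dy pixel offsets added to all coordinates.
#' @return The shifted [ROI-class].
#' @export
shiftROI <- function(roi, dx, dy) {
  if (roi@kind == "rect") {
    rectROI(roi@coords[1] + dx, roi@coords[2] + dy,
            roi@coords[3] + dx, roi@coords[4] + dy,
            dvAxis = roi@dvAxis, label = roi@label, pairId = roi@pairId)
  } else {
    polygonROI(sweep(roi@vertices, 2, c(dx, dy), "+"),
               dvAxis = roi@dvAxis, label = roi@label, pairId = roi@pairId)
  }
}

#' Read and write ROI sets as YAML
#'
#' ROIs are stored as a YAML list of named entries with fields `kind`,
#' `coords` (rect: `[x0, y0, x1, y1]`) or `vertices` (polygon: list of
#' `[x, y]`), `dv_axis`, `label` and `pair_id`.
#'
#' @param path YAML file path.
#' @return `readRois`: a named list of [ROI-class] objects.
#' @export
readRois <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(e) {
    dv <- as.numeric(e$dv_axis %||% c(0, 1))
    pid <- as.character(e$pair_id %||% NA_character_)
    lab <- e$label %||% "whole"
    if (identical(e$kind, "polygon")) {
      polygonROI(do.call(rbind, e$vertices), dvAxis = dv, label = lab,
                 pairId = pid)
    } else {
      co <- as.numeric(e$coords)
      rectROI(co[1], co[2], co[3], co[4], dvAxis = dv, label = lab,
              pairId = pid)
    }
  })
  names(out) <- vapply(seq_along(raw), function(i) {
    raw[[i]]$name %||% names(raw)[i] %||% paste0("roi", i)
  }, character(1))
  out
}

#' @rdname readRois
#' @param rois named list of [ROI-class] objects.
#' @export
writeRois <- function(rois, path) {
  entries <- lapply(seq_along(rois), function(i) {
    r <- rois[[i]]
    e <- list(name = names(rois)[i] %||% paste0("roi", i), kind = r@kind,
              dv_axis = as.numeric(r@dvAxis), label = r@label)
    if (!is.na(r@pairId)) e$pair_id <- r@pairId
    if (r@kind == "rect") {
      e$coords <- as.numeric(r@coords)
    } else {
      e$vertices <- lapply(seq_len(nrow(r@vertices)),
                           function(k) as.numeric(r@vertices[k, ]))
    }
    e
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' Read and write annotated cell-position tables
#'
#' Point patterns are stored as tab-delimited text with header columns
#' `x_um`, `y_um`, `marker`, `region`, plus a YAML sidecar (`<path>.yaml`)
#' holding the region polygon in micrometres.
#'
#' @param path TSV file path.
#' @return `readPointPattern`: a [PointPattern-class].
#' @export
readPointPattern <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("x_um", "y_um", "marker", "region")
  if (!all(need %in% names(tab))) {
    stop("format error: point table must have columns ",
         paste(need, collapse = ", "))
  }
  sc <- .sidecarPath(path)
  if (!file.exists(sc)) {
    stop("configuration error: region polygon sidecar missing: ", sc)
  }
  side <- yaml::read_yaml(sc)
  poly <- do.call(rbind, side$region_polygon_um)
  PointPattern(cbind(tab$x_um, tab$y_um),
               marker = tab$marker[1] %||% "unknown", region = poly)
}

#' @rdname readPointPattern
#' @param pp a [PointPattern-class].
#' @param regionName region label written in the table's `region` column.
#' @export
writePointPattern <- function(pp, path, regionName = "region1") {
  stopifnot(is(pp, "PointPattern"))
  tab <- data.frame(x_um = pp@points[, 1], y_um = pp@points[, 2],
                    marker = rep(pp@marker, nrow(pp@points)),
                    region = rep(regionName, nrow(pp@points)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(region_polygon_um = lapply(
    seq_len(nrow(pp@region)), function(k) as.numeric(pp@region[k, ]))),
    .sidecarPath(path))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
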