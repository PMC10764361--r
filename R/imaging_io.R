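#' Calibrated 2-D projection image
#'
#' A `projection2d` is a numeric pixel matrix (rows = y, columns = x; origin
#' at the top-left, y increasing downward) carrying the in-plane pixel size
#' in micrometres per pixel, the channel label and a free-form provenance
#' record. All micrometre-denominated operations refuse to run on an
#' uncalibrated image (`pixel_size_um = NULL`).
#'
#' @param pixels numeric matrix of non-negative intensities, indexed (y, x).
#' @param pixel_size_um micrometres per pixel (in-plane, isotropic), or
#'   `NULL` for an uncalibrated image.
#' @param channel channel label.
#' @param provenance optional list describing where the image came from.
#' @return An object of class `projection2d` (a matrix with attributes).
#' @export
projection2d <- function(pixels, pixel_size_um = NULL, channel = NA_character_,
                         provenance = NULL) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) abort("`pixels` must be a numeric matrix.")
  if (any(pixels < 0, na.rm = TRUE)) abort("Intensities must be non-negative.")
  if (!is.null(pixel_size_um)) {
    pixel_size_um <- as.numeric(pixel_size_um)
    if (length(pixel_size_um) != 1 || !is.finite(pixel_size_um) ||
        pixel_size_um <= 0) {
      abort("`pixel_size_um` must be a single positive number (or NULL).")
    }
  }
  structure(pixels,
            pixel_size_um = pixel_size_um,
            channel = as.character(channel),
            provenance = provenance,
            class = c("projection2d", "matrix", "array"))
}

#' @export
print.projection2d <- function(x, ...) {
  ps <- attr(x, "pixel_size_um")
  cat(sprintf("<projection2d> %d x %d px, channel '%s', %s\n",
              nrow(x), ncol(x), attr(x, "channel"),
              if (is.null(ps)) "uncalibrated"
              else sprintf("%.4g um/px", ps)))
  invisible(x)
}

#' @rdname projection2d
#' @param x object to test.
#' @export
is_projection2d <- function(x) inherits(x, "projection2d")

#' Pixel calibration of an image
#'
#' @param img a `projection2d` or other object carrying a `pixel_size_um`
#'   attribute.
#' @return The pixel size in micrometres per pixel, or `NULL` if the image is
#'   uncalibrated.
#' @export
pixel_size <- function(img) attr(img, "pixel_size_um")

require_calibration <- function(img, what = "this operation") {
  ps <- pixel_size(img)
  if (is.null(ps)) {
    abort(paste0("Image is uncalibrated (no pixel size in um/px); ", what,
                 " requires calibration. Supply `pixel_size_override` when",
                 " loading, or set the pixel size explicitly."))
  }
  ps
}

#' Multi-channel image stack
#'
#' Container for a confocal stack with axes normalised to
#' (channel, z, y, x). Singleton axes are inserted for missing dimensions.
#'
#' @param voxels 4-D numeric array indexed (channel, z, y, x), or an array of
#'   lower dimension which is promoted by inserting leading singleton axes.
#' @param channel_names character vector, one label per channel.
#' @param pixel_size_um in-plane pixel size (um/px), or `NULL`.
#' @param z_step_um optional z spacing (um/plane).
#' @param provenance optional list recording the source.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, channel_names = NULL, pixel_size_um = NULL,
                        z_step_um = NULL, provenance = NULL) {
  voxels <- as.array(voxels)
  nd <- length(dim(voxels))
  if (nd < 2 || nd > 4) abort("`voxels` must have 2 to 4 dimensions.")
  while (length(dim(voxels)) < 4) {
    voxels <- array(voxels, dim = c(1L, dim(voxels)))
  }
  if (any(voxels < 0, na.rm = TRUE)) abort("Intensities must be non-negative.")
  nch <- dim(voxels)[1]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch))
  if (length(channel_names) != nch) {
    abort(sprintf("`channel_names` has length %d but the stack has %d channels.",
                  length(channel_names), nch))
  }
  if (!is.null(pixel_size_um) && pixel_size_um <= 0) {
    abort("`pixel_size_um` must be positive.")
  }
  structure(list(voxels = voxels,
                 channel_names = as.character(channel_names),
                 pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um,
                 provenance = provenance),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d channel(s) [%s], %d z-plane(s), %d x %d px, %s\n",
              d[1], paste(x$channel_names, collapse = ", "), d[2], d[3], d[4],
              if (is.null(x$pixel_size_um)) "uncalibrated"
              else sprintf("%.4g um/px", x$pixel_size_um)))
  invisible(x)
}

## -- TIFF I/O -----------------------------------------------------------

# Pixel size (um/px) from tiff tag attributes, if derivable. In-plane
# anisotropy is unsupported: a y resolution differing from x is an error.
pixel_size_from_info <- function(info) {
  desc <- info[["description"]]
  if (!is.null(desc) && is.character(desc)) {
    mx <- regmatches(desc, regexec("PhysicalSizeX=\"?([0-9.eE+-]+)\"?", desc))[[1]]
    my <- regmatches(desc, regexec("PhysicalSizeY=\"?([0-9.eE+-]+)\"?", desc))[[1]]
    if (length(mx) == 2 && length(my) == 2 &&
        abs(as.numeric(mx[2]) - as.numeric(my[2])) >
          1e-6 * as.numeric(mx[2])) {
      abort("Anisotropic in-plane pixel sizes are not supported.")
    }
    if (length(mx) == 2) return(as.numeric(mx[2]))
  }
  res <- info[["x.resolution"]]
  resy <- info[["y.resolution"]]
  if (!is.null(res) && !is.null(resy) && is.finite(res) && is.finite(resy) &&
      res > 0 && resy > 0 && abs(res - resy) > 1e-6 * res) {
    abort("Anisotropic in-plane pixel sizes are not supported.")
  }
  unit <- info[["resolution.unit"]]
  if (!is.null(res) && is.finite(res) && res > 0 && !is.null(unit)) {
    if (identical(unit, "cm")) return(1e4 / res)
    if (identical(unit, "inch")) return(25400 / res)
  }
  NULL
}

#' Load a TIFF / OME-TIFF image into an `image_stack`
#'
#' Reads a 2- to 4-dimensional TIFF and normalises its axes to
#' (channel, z, y, x), inserting singleton axes for missing dimensions.
#' Intensities are restored to their integer scale (the `tiff` reader
#' rescales to \[0, 1\]; values are multiplied back by `2^bits - 1`).
#'
#' Pixel calibration is taken, in order of precedence, from
#' `pixel_size_override`, a JSON sidecar (`<path>.json`, as written by
#' [write_projection()] and the synthetic generator), OME `PhysicalSizeX` in
#' the image description, or the TIFF resolution tags. If none is available
#' the stack is uncalibrated and micrometre-denominated operations
#' downstream will refuse to run.
#'
#' Multi-plane files are ambiguous between z-planes and channels; by default
#' planes are treated as z unless a sidecar says otherwise or `axes` is
#' given.
#'
#' @param path path to a TIFF file.
#' @param pixel_size_override pixel size in um/px, overriding any metadata.
#' @param axes for multi-plane files, `"z"` (planes are z-slices, default) or
#'   `"c"` (planes are channels).
#' @param channel_names optional channel labels.
#' @return An [image_stack].
#' @export
load_image <- function(path, pixel_size_override = NULL, axes = NULL,
                       channel_names = NULL) {
  if (!file.exists(path)) abort(sprintf("Cannot read image: '%s' does not exist.", path))
  planes <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                     error = function(e) abort(sprintf("Failed to read '%s': %s",
                                                       path, conditionMessage(e))))
  info <- attributes(planes[[1]])
  bits <- info[["bits.per.sample"]]
  scale <- if (is.null(bits)) 1 else 2^bits - 1

  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else NULL

  ps <- pixel_size_override %||% sidecar$pixel_size_um %||%
    pixel_size_from_info(info)
  if (!is.null(ps)) ps <- as.numeric(ps)

  if (is.null(axes)) {
    axes <- sidecar$axes
    if (is.null(axes) && length(planes) > 1 &&
        length(dim(planes[[1]])) == 2) {
      abort(paste0("Ambiguous axis order: '", path, "' has multiple planes",
                   " and no sidecar metadata. Pass axes = \"z\" (planes are",
                   " z-slices) or axes = \"c\" (planes are channels)."))
    }
    axes <- axes %||% "z"
  }
  if (!axes %in% c("z", "c")) {
    abort("Ambiguous axis order: `axes` must be \"z\" (planes are z-slices) or \"c\" (planes are channels).")
  }

  # Each plane is (y, x) or (y, x, samples); samples are in-plane channels.
  to_chan_list <- function(p) {
    if (length(dim(p)) == 3) lapply(seq_len(dim(p)[3]), function(s) p[, , s])
    else list(p)
  }
  plane_ch <- lapply(planes, to_chan_list)
  nsamp <- length(plane_ch[[1]])
  np <- length(planes)

  if (nsamp > 1) {
    n_c <- nsamp; n_z <- np
    vox <- array(0, dim = c(n_c, n_z, nrow(planes[[1]]), ncol(planes[[1]])))
    for (z in seq_len(n_z)) for (ch in seq_len(n_c)) {
      vox[ch, z, , ] <- plane_ch[[z]][[ch]]
    }
  } else if (axes == "c") {
    n_c <- np; n_z <- 1L
    vox <- array(0, dim = c(n_c, n_z, nrow(planes[[1]]), ncol(planes[[1]])))
    for (ch in seq_len(n_c)) vox[ch, 1, , ] <- plane_ch[[ch]][[1]]
  } else {
    n_c <- 1L; n_z <- np
    vox <- array(0, dim = c(n_c, n_z, nrow(planes[[1]]), ncol(planes[[1]])))
    for (z in seq_len(n_z)) vox[1, z, , ] <- plane_ch[[z]][[1]]
  }
  vox <- round(vox * scale)

  channel_names <- channel_names %||% sidecar$channel_names
  image_stack(vox, channel_names = channel_names, pixel_size_um = ps,
              provenance = list(path = path, bits = bits, axes = axes))
}

#' Maximum-intensity z-projection
#'
#' Collapses one channel of a confocal stack to 2-D by taking, at every
#' (y, x) position, the maximum intensity across z-planes.
#'
#' @param stack an [image_stack].
#' @param channel channel label or 1-based index.
#' @return A [projection2d] with the stack's calibration.
#' @export
max_project <- function(stack, channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) {
    idx <- match(channel, stack$channel_names)
    if (is.na(idx)) {
      abort(sprintf("Unknown channel '%s'. Available channels: %s.",
                    channel, paste(stack$channel_names, collapse = ", ")))
    }
  } else {
    idx <- as.integer(channel)
    if (idx < 1 || idx > dim(stack$voxels)[1]) {
      abort(sprintf("Channel index %d out of range; the stack has %d channels (%s).",
                    idx, dim(stack$voxels)[1],
                    paste(stack$channel_names, collapse = ", ")))
    }
  }
  ch <- stack$voxels[idx, , , , drop = FALSE]
  px <- apply(array(ch, dim = dim(stack$voxels)[2:4]), c(2, 3), max)
  projection2d(px, pixel_size_um = stack$pixel_size_um,
               channel = stack$channel_names[idx],
               provenance = c(stack$provenance,
                              list(projection = "max_intensity")))
}

#' Crop a projection to a rectangular region of interest
#'
#' The same ROI can be reused across a sample set so every image of an
#' analysis is cropped to the equal region of interest.
#'
#' @param img a [projection2d].
#' @param roi integer vector `c(ymin, ymax, xmin, xmax)`, 1-based inclusive
#'   pixel coordinates.
#' @return The cropped [projection2d]; calibration is preserved.
#' @export
crop_projection <- function(img, roi) {
  stopifnot(is_projection2d(img), length(roi) == 4)
  roi <- as.integer(roi)
  if (roi[1] < 1 || roi[3] < 1 || roi[2] > nrow(img) || roi[4] > ncol(img) ||
      roi[1] > roi[2] || roi[3] > roi[4]) {
    abort(sprintf("ROI [y %d-%d, x %d-%d] outside image bounds %d x %d.",
                  roi[1], roi[2], roi[3], roi[4], nrow(img), ncol(img)))
  }
  px <- unclass(img)[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  attributes(px) <- list(dim = dim(px))
  projection2d(px, pixel_size_um = pixel_size(img),
               channel = attr(img, "channel"),
               provenance = c(attr(img, "provenance"), list(roi = roi)))
}

#' Write a projection as a 16-bit TIFF with a JSON calibration sidecar
#'
#' @param img a [projection2d] (or plain matrix).
#' @param path output path (`.tif`); a sidecar `<path>.json` records the
#'   pixel size, channel name and provenance.
#' @param bits bit depth (8 or 16); intensities must fit.
#' @return `path`, invisibly.
#' @export
write_projection <- function(img, path, bits = 16) {
  px <- unclass(as.matrix(img))
  maxv <- 2^bits - 1
  if (max(px) > maxv) abort(sprintf("Intensities exceed %d-bit range.", bits))
  tiff::writeTIFF(px / maxv, path, bits.per.sample = as.integer(bits))
  jsonlite::write_json(
    list(pixel_size_um = pixel_size(img),
         channel_names = attr(img, "channel"),
         axes = "z",
         provenance = attr(img, "provenance")),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalise the sprout growth axis to +y
#'
#' All morphometry assumes sprouts grow toward increasing y (downward).
#' Chips imaged in another orientation are flipped/rotated here once,
#' immediately after projection.
#'
#' @param img a [projection2d].
#' @param growth_axis the direction sprouts grow in the source image:
#'   `"+y"` (no change), `"-y"`, `"+x"` or `"-x"`.
#' @return The reoriented [projection2d].
#' @export
orient_growth_axis <- function(img, growth_axis = c("+y", "-y", "+x", "-x")) {
  growth_axis <- match.arg(growth_axis)
  px <- unclass(as.matrix(img))
  attributes(px) <- list(dim = dim(px))
  out <- switch(growth_axis,
    "+y" = px,
    "-y" = px[rev(seq_len(nrow(px))), , drop = FALSE],
    "+x" = t(px),
    "-x" = t(px)[rev(seq_len(ncol(px))), , drop = FALSE])
  if (is_projection2d(img)) {
    projection2d(out, pixel_size_um = pixel_size(img),
                 channel = attr(img, "channel"),
                 provenance = c(attr(img, "provenance"),
                                list(growth_axis = growth_axis)))
  } else out
}
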