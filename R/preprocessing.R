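#' Preprocessing configuration for sprout segmentation
#'
#' One configuration applies to every image of an analysis set, so the
#' identical threshold is used for all images (set-level thresholding).
#'
#' @param gaussian_sigma_px standard deviation of the Gaussian denoising
#'   filter, in pixels (0 disables smoothing).
#' @param threshold_mode `"otsu_pooled"` computes a single Otsu threshold
#'   from the pooled histogram of all images in the set; `"fixed"` uses
#'   `threshold_value` directly.
#' @param threshold_value intensity threshold, required when
#'   `threshold_mode = "fixed"`.
#' @param min_blob_area_px connected foreground components smaller than this
#'   (in pixels) are removed from the mask.
#' @param connectivity pixel connectivity for components, 4 or 8.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(gaussian_sigma_px = 2,
                              threshold_mode = c("otsu_pooled", "fixed"),
                              threshold_value = NULL,
                              min_blob_area_px = 200,
                              connectivity = 8) {
  threshold_mode <- match.arg(threshold_mode)
  if (gaussian_sigma_px < 0) abort("`gaussian_sigma_px` must be >= 0.")
  if (min_blob_area_px < 0) abort("`min_blob_area_px` must be >= 0.")
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  if (threshold_mode == "fixed" && is.null(threshold_value)) {
    abort("threshold_mode = \"fixed\" requires `threshold_value`.")
  }
  structure(list(gaussian_sigma_px = gaussian_sigma_px,
                 threshold_mode = threshold_mode,
                 threshold_value = threshold_value,
                 min_blob_area_px = as.integer(min_blob_area_px),
                 connectivity = as.integer(connectivity)),
            class = "preprocess_config")
}

#' Gaussian denoising with reflective boundaries
#'
#' Smooths a projection with a separable isotropic Gaussian kernel
#' (truncated at 4 sigma, renormalised). Boundaries are mirror-reflected,
#' so total intensity is conserved; `sigma_px = 0` returns the input
#' unchanged.
#'
#' @param img a [projection2d] (or numeric matrix).
#' @param sigma_px Gaussian standard deviation in pixels, >= 0.
#' @return The smoothed image with attributes preserved.
#' @export
gaussian_denoise <- function(img, sigma_px) {
  if (sigma_px < 0) abort("`sigma_px` must be >= 0.")
  if (sigma_px == 0) return(img)
  px <- unclass(as.matrix(img))
  attributes(px) <- list(dim = dim(px))
  out <- cpp_gaussian_blur(px, sigma_px)
  if (is_projection2d(img)) {
    projection2d(pmax(out, 0), pixel_size_um = pixel_size(img),
                 channel = attr(img, "channel"),
                 provenance = attr(img, "provenance"))
  } else pmax(out, 0)
}

#' Pooled intensity histogram over an image set
#'
#' @param imgs list of projections / matrices from one analysis set.
#' @param n_bins number of histogram bins.
#' @return A list with `counts`, `mids` and `breaks`, usable by
#'   [otsu_from_histogram()] and [binarize()].
#' @export
pooled_histogram <- function(imgs, n_bins = 256) {
  if (is.matrix(imgs)) imgs <- list(imgs)
  vals <- unlist(lapply(imgs, function(m) {
    m <- unclass(as.matrix(m))
    dim(m) <- NULL
    m
  }), use.names = FALSE)
  rng <- range(vals)
  if (rng[1] == rng[2]) rng[2] <- rng[1] + 1
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(findInterval(vals, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  list(counts = counts, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       breaks = breaks)
}

#' Otsu threshold from a (pooled) histogram
#'
#' Maximises between-class variance over the histogram bins and returns the
#' midpoint intensity of the optimal split, so one threshold can be derived
#' from the pooled histogram of a whole analysis set.
#'
#' @param hist a histogram as returned by [pooled_histogram()].
#' @return A single threshold intensity.
#' @export
otsu_from_histogram <- function(hist) {
  counts <- as.numeric(hist$counts); mids <- hist$mids
  total <- sum(counts)
  if (total == 0) abort("Empty histogram.")
  w <- counts / total
  mu <- cumsum(w * mids)
  omega <- cumsum(w)
  mu_t <- mu[length(mu)]
  denom <- omega * (1 - omega)
  sigma_b <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, NA)
  k <- which.max(sigma_b)
  hist$breaks[k + 1]
}

#' Threshold a projection into a binary sprout mask
#'
#' A pixel is foreground iff its intensity is strictly greater than the
#' threshold. With `threshold_mode = "otsu_pooled"` the threshold is derived
#' once from the pooled histogram of the analysis set (`set_histogram`), so
#' the identical threshold value applies to every image of the set.
#'
#' @param img a [projection2d] (or matrix), typically already denoised.
#' @param cfg a [preprocess_config()].
#' @param set_histogram pooled histogram from [pooled_histogram()], required
#'   for `threshold_mode = "otsu_pooled"`.
#' @return A logical matrix of class `binary_mask` with the calibration and
#'   config attached.
#' @export
binarize <- function(img, cfg = preprocess_config(), set_histogram = NULL) {
  stopifnot(inherits(cfg, "preprocess_config"))
  thr <- switch(cfg$threshold_mode,
    fixed = cfg$threshold_value %||%
      abort("threshold_mode = \"fixed\" requires `threshold_value`."),
    otsu_pooled = {
      if (is.null(set_histogram)) {
        abort(paste0("threshold_mode = \"otsu_pooled\" requires the pooled",
                     " histogram of the analysis set (`set_histogram`)."))
      }
      otsu_from_histogram(set_histogram)
    })
  px <- unclass(as.matrix(img))
  m <- px > thr
  binary_mask(m, pixel_size_um = pixel_size(img), config = cfg,
              threshold = thr)
}

binary_mask <- function(m, pixel_size_um = NULL, config = NULL,
                        threshold = NULL) {
  structure(m, pixel_size_um = pixel_size_um, config_used = config,
            threshold = threshold,
            class = c("binary_mask", "matrix", "array"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground px\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Remove small foreground blobs from a mask
#'
#' Deletes every connected foreground component whose area (pixel count) is
#' below `min_area_px`; larger components are untouched. Used to clear
#' debris and filter speckle before skeletonization. Idempotent.
#'
#' @param mask a logical matrix / `binary_mask`.
#' @param min_area_px minimum surviving component area in pixels.
#' @param connectivity 4 or 8.
#' @return The filtered mask, attributes preserved.
#' @export
remove_small_blobs <- function(mask, min_area_px, connectivity = 8) {
  m <- unclass(mask) == TRUE
  if (min_area_px <= 0 || !any(m)) return(mask)
  lab <- cpp_label_components(m, as.integer(connectivity))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px)
  out <- matrix(lab %in% keep & m, nrow(m), ncol(m))
  binary_mask(out, pixel_size_um = attr(mask, "pixel_size_um"),
              config = attr(mask, "config_used"),
              threshold = attr(mask, "threshold"))
}

#' Label individual sprouts in a mask
#'
#' Labels 8-connected foreground components, orders labels by descending
#' area, and flags each component as root-attached if it intersects the
#' root band (the strip `y <= root_band_px` adjoining the endothelial
#' monolayer; the growth axis is assumed canonical +y).
#'
#' @param mask a `binary_mask` (post blob-removal).
#' @param root_band_px height in pixels of the root-edge band.
#' @return A list of class `sprout_labels` with `labels` (integer matrix,
#'   0 = background) and `info`, a tibble with one row per component:
#'   `label`, `area_px`, `root_attached`, and bounding box columns.
#' @export
label_sprouts <- function(mask, root_band_px = 20) {
  m <- unclass(mask) == TRUE
  lab <- cpp_label_components(m, 8L)
  k <- max(lab)
  if (k == 0) {
    info <- tibble(label = integer(), area_px = integer(),
                   root_attached = logical(), ymin = integer(),
                   ymax = integer(), xmin = integer(), xmax = integer())
    return(structure(list(labels = lab, info = info,
                          root_band_px = as.integer(root_band_px),
                          pixel_size_um = attr(mask, "pixel_size_um")),
                     class = "sprout_labels"))
  }
  areas <- tabulate(lab[lab > 0], nbins = k)
  ord <- order(areas, decreasing = TRUE)
  remap <- integer(k); remap[ord] <- seq_len(k)
  lab[lab > 0] <- remap[lab[lab > 0]]
  areas <- areas[ord]

  idx <- which(lab > 0)
  ys <- (idx - 1) %% nrow(lab) + 1
  xs <- (idx - 1) %/% nrow(lab) + 1
  lv <- lab[idx]
  info <- tibble(label = lv, y = ys, x = xs) |>
    group_by(.data$label) |>
    summarise(area_px = dplyr::n(),
              root_attached = any(.data$y <= root_band_px),
              ymin = min(.data$y), ymax = max(.data$y),
              xmin = min(.data$x), xmax = max(.data$x),
              .groups = "drop") |>
    arrange(.data$label)
  structure(list(labels = lab, info = info,
                 root_band_px = as.integer(root_band_px),
                 pixel_size_um = attr(mask, "pixel_size_um")),
            class = "sprout_labels")
}

#' @export
print.sprout_labels <- function(x, ...) {
  cat(sprintf("<sprout_labels> %d component(s), %d root-attached\n",
              nrow(x$info), sum(x$info$root_attached)))
  invisible(x)
}
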