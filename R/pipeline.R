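#' Measure one sprout image
#'
#' Runs the full morphometry chain on a single projection: Gaussian
#' denoising, thresholding (a fixed or precomputed set-level threshold),
#' small-blob removal, sprout labelling, skeletonization and feature
#' extraction.
#'
#' @param img sprout-channel [projection2d].
#' @param cfg a [preprocess_config()].
#' @param set_histogram pooled histogram for `otsu_pooled` thresholding
#'   (computed from this image alone if omitted - only appropriate for
#'   single-image analyses).
#' @param root_band_px root-band height (px).
#' @param sample_id,condition identifiers for the output row.
#' @return A one-row feature tibble; the intermediate `mask`, `labels` and
#'   `skeleton` are attached as attributes for QC.
#' @export
measure_sample <- function(img, cfg = preprocess_config(),
                           set_histogram = NULL, root_band_px = 20,
                           sample_id = NA_character_,
                           condition = NA_character_) {
  den <- gaussian_denoise(img, cfg$gaussian_sigma_px)
  if (cfg$threshold_mode == "otsu_pooled" && is.null(set_histogram)) {
    set_histogram <- pooled_histogram(list(den))
  }
  mask <- binarize(den, cfg, set_histogram)
  mask <- remove_small_blobs(mask, cfg$min_blob_area_px, cfg$connectivity)
  labels <- label_sprouts(mask, root_band_px)
  skel <- skeletonize_mask(mask, labels)
  feats <- compute_features(mask, skel, labels, sample_id = sample_id,
                            condition = condition)
  attr(feats, "mask") <- mask
  attr(feats, "labels") <- labels
  attr(feats, "skeleton") <- skel
  feats
}

#' Measure a set of sprout images with one shared threshold
#'
#' Denoises every image, derives a single set-level threshold from the
#' pooled histogram (for `otsu_pooled` mode), and measures each image,
#' returning the per-sample feature table.
#'
#' @param imgs named list of sprout-channel projections (names become
#'   sample ids), or a `generate_condition_set()` result whose sprout
#'   channels and manifest are used directly.
#' @param cfg a [preprocess_config()].
#' @param root_band_px root-band height (px).
#' @param conditions optional character vector of condition labels, one per
#'   image.
#' @return A feature tibble with one row per sample.
#' @export
measure_dataset <- function(imgs, cfg = preprocess_config(),
                            root_band_px = 20, conditions = NULL) {
  if (is.list(imgs) && !is.null(imgs$samples) && !is.null(imgs$manifest)) {
    conditions <- imgs$manifest$condition
    ids <- imgs$manifest$sample_id
    imgs <- lapply(imgs$samples, function(s) s$channels$sprout)
    names(imgs) <- ids
  }
  ids <- names(imgs) %||% sprintf("s%03d", seq_along(imgs))
  if (is.null(conditions)) conditions <- rep(NA_character_, length(imgs))
  den <- lapply(imgs, gaussian_denoise, sigma_px = cfg$gaussian_sigma_px)
  hist <- if (cfg$threshold_mode == "otsu_pooled") pooled_histogram(den) else NULL
  rows <- purrr::map(seq_along(den), function(i) {
    measure_sample(den[[i]],
                   cfg = preprocess_config(gaussian_sigma_px = 0,
                                           threshold_mode = cfg$threshold_mode,
                                           threshold_value = cfg$threshold_value,
                                           min_blob_area_px = cfg$min_blob_area_px,
                                           connectivity = cfg$connectivity),
                   set_histogram = hist, root_band_px = root_band_px,
                   sample_id = ids[i], condition = conditions[i])
  })
  dplyr::bind_rows(lapply(rows, function(r) { attributes(r)[c("mask", "labels", "skeleton")] <- NULL; r }))
}

#' Profile LC3B puncta for every sprout of a sample
#'
#' Segments the sprout channel, detects puncta on the LC3B channel, and
#' computes one radial profile per root-attached sprout that has both a
#' retained tip endpoint and at least one punctum.
#'
#' @param sprout_img,lc3b_img aligned projections.
#' @param cfg a [preprocess_config()].
#' @param set_histogram optional pooled histogram for the sprout channel.
#' @param root_band_px root-band height (px).
#' @param bin_width_um contour interval (um).
#' @param metric `"intensity_sum"` or `"pixel_count"`.
#' @param relative if `TRUE`, re-bin each profile to percent of that
#'   sprout's measured length (`bin_percent` bins).
#' @param bin_percent relative bin width in percent.
#' @param restrict_to_mask profile only puncta pixels inside the sprout
#'   mask.
#' @return List of `radial_profile` tibbles (one per profiled sprout), with
#'   the measured feature row as attribute `features`.
#' @export
profile_sprouts <- function(sprout_img, lc3b_img, cfg = preprocess_config(),
                            set_histogram = NULL, root_band_px = 20,
                            bin_width_um = 10,
                            metric = c("intensity_sum", "pixel_count"),
                            relative = FALSE, bin_percent = 5,
                            restrict_to_mask = TRUE) {
  metric <- match.arg(metric)
  feats <- measure_sample(sprout_img, cfg, set_histogram, root_band_px)
  mask <- attr(feats, "mask")
  labels <- attr(feats, "labels")
  skel <- attr(feats, "skeleton")
  puncta <- detect_puncta(lc3b_img, labels)
  ps <- pixel_size(sprout_img)

  rooted <- labels$info$label[labels$info$root_attached]
  profiles <- list()
  for (l in rooted) {
    if (!any(!is.na(puncta$sprout) & puncta$sprout == l)) next
    tip <- select_tip_endpoint(skel, l)
    if (is.null(tip)) next
    pr <- radial_profile(puncta, tip, bin_width_um = bin_width_um,
                         sprout = l,
                         sprout_mask = if (restrict_to_mask) labels$labels == l else NULL,
                         metric = metric, pixel_size_um = ps)
    if (relative) {
      len_um <- sprout_skeleton_length_um(skel, labels, l, ps)
      if (is.na(len_um) || len_um <= 0) next
      pr <- to_relative_profile(pr, len_um, bin_percent)
    }
    profiles[[as.character(l)]] <- pr
  }
  attr(profiles, "features") <- feats
  attr(profiles, "puncta") <- puncta
  profiles
}

# Skeleton pixel count of one labelled sprout, in micrometres.
sprout_skeleton_length_um <- function(skel, labels, label, ps) {
  n <- sum(!is.na(skel$coords$label) & skel$coords$label == label)
  if (n == 0) return(NA_real_)
  n * ps
}
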