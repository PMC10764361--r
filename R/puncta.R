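#' Detect LC3B puncta in a fluorescence channel
#'
#' Threshold, 8-connected component labelling, and an area-range filter.
#' The default threshold is the robust background rule
#' `median + 5 * MAD` of the channel. Each punctum gets an
#' intensity-weighted centroid and, when sprout labels are supplied, the
#' sprout label underlying that centroid (0 = unassigned / background).
#'
#' @param lc3b a [projection2d] of the puncta channel (cropped identically
#'   to the sprout channel).
#' @param labels optional [label_sprouts()] result from the sprout channel.
#' @param threshold intensity threshold; pixels strictly above it are
#'   candidate puncta pixels. `NULL` uses `median + 5 * MAD`.
#' @param min_area_px,max_area_px punctum area range in pixels (inclusive).
#' @return A tibble of class `puncta_set`, one row per punctum: `punctum`,
#'   `y`, `x` (weighted centroid), `area_px`, `total_intensity`, `sprout`.
#'   The per-pixel records back the profiling and are kept in attribute
#'   `pixel_data` (tibble `punctum`, `y`, `x`, `intensity`, `sprout`).
#' @export
detect_puncta <- function(lc3b, labels = NULL, threshold = NULL,
                          min_area_px = 4, max_area_px = 400) {
  px <- unclass(as.matrix(lc3b))
  if (is.null(threshold)) {
    threshold <- median(px) + 5 * mad(px)
  }
  m <- px > threshold
  empty <- tibble(punctum = integer(), y = numeric(), x = numeric(),
                  area_px = integer(), total_intensity = numeric(),
                  sprout = integer())
  mk <- function(tbl, pixdat) {
    attr(tbl, "pixel_data") <- pixdat
    attr(tbl, "threshold") <- threshold
    attr(tbl, "pixel_size_um") <- pixel_size(lc3b)
    class(tbl) <- c("puncta_set", class(tbl))
    tbl
  }
  if (!any(m)) {
    return(mk(empty, tibble(punctum = integer(), y = integer(), x = integer(),
                            intensity = numeric(), sprout = integer())))
  }
  lab <- cpp_label_components(m, 8L)
  idx <- which(m)
  pix <- tibble(comp = lab[idx],
                y = (idx - 1) %% nrow(px) + 1,
                x = (idx - 1) %/% nrow(px) + 1,
                intensity = px[idx])
  comp_stats <- pix |>
    group_by(.data$comp) |>
    summarise(area_px = dplyr::n(),
              total_intensity = sum(.data$intensity),
              cy = sum(.data$y * .data$intensity) / sum(.data$intensity),
              cx = sum(.data$x * .data$intensity) / sum(.data$intensity),
              .groups = "drop") |>
    filter(.data$area_px >= min_area_px, .data$area_px <= max_area_px) |>
    arrange(.data$comp)
  if (nrow(comp_stats) == 0) {
    return(mk(empty, tibble(punctum = integer(), y = integer(), x = integer(),
                            intensity = numeric(), sprout = integer())))
  }
  comp_stats$punctum <- seq_len(nrow(comp_stats))
  sprout_of <- function(cy, cx) {
    if (is.null(labels)) return(NA_integer_)
    labels$labels[cbind(pmin(pmax(round(cy), 1), nrow(labels$labels)),
                        pmin(pmax(round(cx), 1), ncol(labels$labels)))]
  }
  comp_stats$sprout <- as.integer(sprout_of(comp_stats$cy, comp_stats$cx))
  out <- tibble(punctum = comp_stats$punctum,
                y = comp_stats$cy, x = comp_stats$cx,
                area_px = comp_stats$area_px,
                total_intensity = comp_stats$total_intensity,
                sprout = comp_stats$sprout)
  pixdat <- pix |>
    dplyr::inner_join(comp_stats[, c("comp", "punctum", "sprout")],
                      by = "comp") |>
    dplyr::select("punctum", "y", "x", "intensity", "sprout")
  mk(out, pixdat)
}

#' Intensity-weighted centre of gravity of puncta
#'
#' Weighted mean position over all puncta pixels, optionally restricted to
#' one sprout.
#'
#' @param puncta a `puncta_set`.
#' @param sprout optional sprout label to restrict to.
#' @return Named numeric `c(y, x)`, or `c(NA, NA)` when no puncta qualify.
#' @export
puncta_center_of_gravity <- function(puncta, sprout = NULL) {
  pix <- attr(puncta, "pixel_data")
  if (!is.null(sprout)) pix <- pix[!is.na(pix$sprout) & pix$sprout == sprout, ]
  if (nrow(pix) == 0 || sum(pix$intensity) == 0) return(c(y = NA_real_, x = NA_real_))
  c(y = sum(pix$y * pix$intensity) / sum(pix$intensity),
    x = sum(pix$x * pix$intensity) / sum(pix$intensity))
}

#' Select the tip endpoint of a sprout
#'
#' Among the endpoints retained by the sample-wide median-y filter that
#' belong to the given sprout, returns the one with maximal y (farthest
#' from the root edge), breaking ties by smaller x. Returns `NULL` when the
#' sprout has no retained endpoint (such sprouts are excluded from
#' profiling).
#'
#' @param skel a `skeleton_graph` built with sprout labels.
#' @param sprout sprout label.
#' @return Named numeric `c(y, x)`, or `NULL`.
#' @export
select_tip_endpoint <- function(skel, sprout) {
  ep <- filter_endpoints_median_y(detect_endpoints(skel))
  ep <- ep[!is.na(ep$label) & ep$label == sprout, , drop = FALSE]
  if (nrow(ep) == 0) return(NULL)
  ep <- ep[order(-ep$y, ep$x), ]
  c(y = ep$y[1], x = ep$x[1])
}

#' Radial puncta profile from a sprout endpoint
#'
#' Assigns every puncta pixel (within the sprout mask, when given) to a
#' distance bin by its Euclidean distance from the endpoint, converted to
#' micrometres; bin `[k*w, (k+1)*w)` collects pixels with
#' `floor(d / w) = k`. Per bin, the value is the summed pixel intensity
#' (`metric = "intensity_sum"`) or the pixel count
#' (`metric = "pixel_count"`). The reference line from the endpoint through
#' the puncta centre of gravity is stored for visualization only.
#'
#' @param puncta a `puncta_set` (carrying pixel-level data).
#' @param endpoint named numeric `c(y, x)` from [select_tip_endpoint()].
#' @param bin_width_um contour interval in micrometres (default 10).
#' @param sprout optional sprout label: restrict to that sprout's puncta.
#' @param sprout_mask optional logical matrix: only pixels inside it are
#'   profiled.
#' @param metric `"intensity_sum"` or `"pixel_count"`.
#' @param pixel_size_um calibration override; defaults to the puncta set's.
#' @return A tibble of class `radial_profile`: `bin_low_um`, `bin_high_um`,
#'   `bin_mid_um`, `value`. Attributes: `mode = "absolute_um"`, `metric`,
#'   `endpoint`, `reference_line`, and `pixel_distances` (per-pixel tibble
#'   used for relative re-binning).
#' @export
radial_profile <- function(puncta, endpoint, bin_width_um = 10,
                           sprout = NULL, sprout_mask = NULL,
                           metric = c("intensity_sum", "pixel_count"),
                           pixel_size_um = NULL) {
  metric <- match.arg(metric)
  ps <- pixel_size_um %||% attr(puncta, "pixel_size_um")
  if (is.null(ps)) {
    abort("Radial profiling in micrometres requires pixel calibration.")
  }
  pix <- attr(puncta, "pixel_data")
  if (!is.null(sprout)) pix <- pix[!is.na(pix$sprout) & pix$sprout == sprout, ]
  if (!is.null(sprout_mask)) {
    keep <- unclass(sprout_mask)[cbind(pix$y, pix$x)] == TRUE
    pix <- pix[keep, , drop = FALSE]
  }
  d_um <- if (nrow(pix)) {
    sqrt((pix$y - endpoint[["y"]])^2 + (pix$x - endpoint[["x"]])^2) * ps
  } else numeric()
  w <- if (metric == "intensity_sum") pix$intensity else rep(1, nrow(pix))

  n_bins <- if (length(d_um)) max(floor(d_um / bin_width_um)) + 1 else 1
  bin <- if (length(d_um)) floor(d_um / bin_width_um) else integer()
  value <- vapply(seq_len(n_bins) - 1, function(k) sum(w[bin == k]), numeric(1))
  out <- tibble(bin_low_um = (seq_len(n_bins) - 1) * bin_width_um,
                bin_high_um = seq_len(n_bins) * bin_width_um,
                bin_mid_um = ((seq_len(n_bins) - 1) + 0.5) * bin_width_um,
                value = value)
  cog <- puncta_center_of_gravity(puncta, sprout)
  attr(out, "mode") <- "absolute_um"
  attr(out, "metric") <- metric
  attr(out, "bin_width") <- bin_width_um
  attr(out, "endpoint") <- endpoint
  attr(out, "reference_line") <- list(from = endpoint, to = cog)
  attr(out, "pixel_distances") <- tibble(d_um = d_um, weight = w)
  class(out) <- c("radial_profile", class(out))
  out
}

#' Re-express a radial profile in percent of sprout length
#'
#' Each measured pixel's distance is re-expressed as `100 * d / L` and
#' re-binned into bins of width `bin_percent`; total signal is conserved
#' exactly.
#'
#' @param profile a `radial_profile` (absolute mode).
#' @param sprout_length_um sprout length L in micrometres, > 0.
#' @param bin_percent relative bin width in percent (default 5).
#' @return A `radial_profile` tibble in relative mode: `bin_low_pct`,
#'   `bin_high_pct`, `bin_mid_pct`, `value`.
#' @export
to_relative_profile <- function(profile, sprout_length_um, bin_percent = 5) {
  if (!is.finite(sprout_length_um) || sprout_length_um <= 0) {
    abort("`sprout_length_um` must be > 0.")
  }
  pix <- attr(profile, "pixel_distances")
  rel <- 100 * pix$d_um / sprout_length_um
  n_bins <- if (length(rel)) max(floor(rel / bin_percent)) + 1 else 1
  bin <- if (length(rel)) floor(rel / bin_percent) else integer()
  value <- vapply(seq_len(n_bins) - 1,
                  function(k) sum(pix$weight[bin == k]), numeric(1))
  out <- tibble(bin_low_pct = (seq_len(n_bins) - 1) * bin_percent,
                bin_high_pct = seq_len(n_bins) * bin_percent,
                bin_mid_pct = ((seq_len(n_bins) - 1) + 0.5) * bin_percent,
                value = value)
  attr(out, "mode") <- "relative_percent"
  attr(out, "metric") <- attr(profile, "metric")
  attr(out, "bin_width") <- bin_percent
  attr(out, "endpoint") <- attr(profile, "endpoint")
  class(out) <- c("radial_profile", class(out))
  out
}

#' Aggregate radial profiles across sprouts
#'
#' Profiles must share mode, metric and bin width; shorter profiles are
#' zero-extended to the longest. `mode = "sum"` gives the per-bin sum over
#' sprouts; `mode = "mean_sem"` the per-bin mean and standard error
#' (sd / sqrt(n)).
#'
#' @param profiles list of `radial_profile` tibbles.
#' @param mode `"sum"` or `"mean_sem"`.
#' @return A tibble of class `aggregate_profile` with bin columns plus
#'   `value` (sum) or `mean`, `sem`, and `n_sprouts`.
#' @export
aggregate_profiles <- function(profiles, mode = c("sum", "mean_sem")) {
  mode <- match.arg(mode)
  stopifnot(length(profiles) >= 1)
  bw <- unique(vapply(profiles, function(p) attr(p, "bin_width"), numeric(1)))
  md <- unique(vapply(profiles, function(p) attr(p, "mode"), character(1)))
  mt <- unique(vapply(profiles, function(p) attr(p, "metric"), character(1)))
  if (length(bw) != 1 || length(md) != 1 || length(mt) != 1) {
    abort("All profiles must share bin width, mode and metric.")
  }
  n_bins <- max(vapply(profiles, nrow, integer(1)))
  vals <- vapply(profiles, function(p) c(p$value, rep(0, n_bins - nrow(p))),
                 numeric(n_bins))
  vals <- matrix(vals, nrow = n_bins)
  low <- (seq_len(n_bins) - 1) * bw
  out <- tibble(bin_low = low, bin_high = low + bw, bin_mid = low + bw / 2)
  names(out) <- if (md == "absolute_um") {
    c("bin_low_um", "bin_high_um", "bin_mid_um")
  } else {
    c("bin_low_pct", "bin_high_pct", "bin_mid_pct")
  }
  n <- length(profiles)
  if (mode == "sum") {
    out$value <- rowSums(vals)
  } else {
    out$mean <- rowMeans(vals)
    out$sem <- if (n >= 2) apply(vals, 1, sd) / sqrt(n) else NA_real_
  }
  out$n_sprouts <- n
  attr(out, "mode") <- md
  attr(out, "metric") <- mt
  attr(out, "bin_width") <- bw
  attr(out, "aggregate") <- mode
  class(out) <- c("aggregate_profile", class(out))
  out
}

#' Count sprouts containing at least one punctum
#'
#' @param puncta a `puncta_set` with sprout assignments.
#' @param labels the [label_sprouts()] result; only root-attached sprouts
#'   are counted.
#' @return Integer count of root-attached sprout labels owning >= 1
#'   punctum.
#' @export
count_puncta_positive_sprouts <- function(puncta, labels) {
  rooted <- labels$info$label[labels$info$root_attached]
  length(intersect(unique(puncta$sprout[!is.na(puncta$sprout)]), rooted))
}

#' mCherry/GFP dual-reporter flux ratio in a region
#'
#' For each channel, sums intensities of pixels strictly above that
#' channel's threshold inside the region mask; the ratio
#' mCherry / GFP reports autophagic flux (GFP is quenched in acidic
#' autolysosomes). A zero GFP signal flags the ratio as missing.
#'
#' @param mcherry,gfp aligned [projection2d] channels.
#' @param region_mask logical matrix defining the region (e.g. from
#'   [region_masks()]).
#' @param threshold_mcherry,threshold_gfp per-channel positivity
#'   thresholds; `NULL` uses `median + 5 * MAD` of the channel.
#' @param metric `"intensity_sum"` or `"pixel_count"`.
#' @param region optional region label carried into the row.
#' @return One-row tibble: `region`, `mcherry_signal`, `gfp_signal`,
#'   `ratio`.
#' @export
dual_reporter_ratio <- function(mcherry, gfp, region_mask,
                                threshold_mcherry = NULL,
                                threshold_gfp = NULL,
                                metric = c("intensity_sum", "pixel_count"),
                                region = NA_character_) {
  metric <- match.arg(metric)
  mc <- unclass(as.matrix(mcherry)); gf <- unclass(as.matrix(gfp))
  if (!all(dim(mc) == dim(gf)) || !all(dim(mc) == dim(region_mask))) {
    abort("mCherry, GFP and region mask must have identical dimensions.")
  }
  thr_mc <- threshold_mcherry %||% (median(mc) + 5 * mad(mc))
  thr_gf <- threshold_gfp %||% (median(gf) + 5 * mad(gf))
  rm <- unclass(region_mask) == TRUE
  signal <- function(px, thr) {
    pos <- rm & px > thr
    if (metric == "intensity_sum") sum(px[pos]) else sum(pos)
  }
  ms <- signal(mc, thr_mc)
  gs <- signal(gf, thr_gf)
  tibble(region = region, mcherry_signal = ms, gfp_signal = gs,
         ratio = if (gs > 0) ms / gs else NA_real_)
}

#' Basement and leading region masks
#'
#' Rule-based sub-regions per root-attached sprout: the basement region is
#' the root-proximal fraction `f` of each sprout's y-extent, the leading
#' region the tip-proximal fraction `f`.
#'
#' @param labels a [label_sprouts()] result.
#' @param fraction fraction `f` of each sprout's extent (default 0.25).
#' @return List with logical matrices `basement` and `leading`.
#' @export
region_masks <- function(labels, fraction = 0.25) {
  lab <- labels$labels
  basement <- matrix(FALSE, nrow(lab), ncol(lab))
  leading <- matrix(FALSE, nrow(lab), ncol(lab))
  info <- labels$info[labels$info$root_attached, , drop = FALSE]
  yy <- matrix(seq_len(nrow(lab)), nrow(lab), ncol(lab))
  for (i in seq_len(nrow(info))) {
    l <- info$label[i]
    h <- info$ymax[i] - info$ymin[i] + 1
    cut_b <- info$ymin[i] + ceiling(fraction * h) - 1
    cut_l <- info$ymax[i] - ceiling(fraction * h) + 1
    basement <- basement | (lab == l & yy <= cut_b)
    leading <- leading | (lab == l & yy >= cut_l)
  }
  list(basement = basement, leading = leading)
}
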