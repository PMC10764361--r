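#' Plot a radial puncta profile
#'
#' @param object a `radial_profile` or `aggregate_profile` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot radial_profile
#' @export
autoplot.radial_profile <- function(object, ...) {
  md <- attr(object, "mode")
  xcol <- if (identical(md, "absolute_um")) "bin_mid_um" else "bin_mid_pct"
  xlab <- if (identical(md, "absolute_um")) {
    "Distance from sprout endpoint (µm)"
  } else "Distance from sprout endpoint (% of length)"
  ylab <- if (identical(attr(object, "metric"), "pixel_count")) {
    "Puncta pixels"
  } else "Summed puncta intensity"
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[xcol]], y = .data$value)) +
    ggplot2::geom_col(width = attr(object, "bin_width") * 0.9,
                      fill = "firebrick") +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.radial_profile
#' @method autoplot aggregate_profile
#' @export
autoplot.aggregate_profile <- function(object, ...) {
  md <- attr(object, "mode")
  xcol <- if (identical(md, "absolute_um")) "bin_mid_um" else "bin_mid_pct"
  xlab <- if (identical(md, "absolute_um")) {
    "Distance from sprout endpoint (µm)"
  } else "Distance from sprout endpoint (% of length)"
  ycol <- if (identical(attr(object, "aggregate"), "sum")) "value" else "mean"
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data[[xcol]], y = .data[[ycol]])) +
    ggplot2::geom_col(width = attr(object, "bin_width") * 0.9,
                      fill = "firebrick") +
    ggplot2::labs(x = xlab, y = paste0(
      if (identical(attr(object, "metric"), "pixel_count")) "Puncta pixels"
      else "Puncta intensity",
      if (identical(attr(object, "aggregate"), "sum")) " (sum over sprouts)"
      else " (mean ± SEM)")) +
    ggplot2::theme_minimal()
  if (identical(attr(object, "aggregate"), "mean_sem") &&
      any(is.finite(object$sem))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = attr(object, "bin_width") * 0.3)
  }
  p
}

#' Bar chart of a per-condition metric summary
#'
#' Mean with SD (or SEM) error bars and per-sample points, the standard
#' reporting style for sprout morphology panels.
#'
#' @param table feature tibble (one row per sample).
#' @param metric numeric column to plot.
#' @param group grouping column.
#' @param dispersion `"sd"` or `"sem"`.
#' @return A ggplot.
#' @export
plot_metric_by_condition <- function(table, metric, group = "condition",
                                     dispersion = c("sd", "sem")) {
  dispersion <- match.arg(dispersion)
  sm <- summarize_features(table, metric, group, dispersion)
  err <- sm[[dispersion]]
  sm$ymin <- sm$mean - err
  sm$ymax <- sm$mean + err
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "black", width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ymin, ymax = .data$ymax),
                           width = 0.25) +
    ggplot2::geom_jitter(
      data = tibble(condition = as.character(table[[group]]),
                    mean = table[[metric]]),
      width = 0.12, size = 1, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_classic()
}

#' QC overlay of mask, skeleton and puncta
#'
#' Raster plot of the sprout channel with the skeleton, retained endpoints
#' and detected puncta centroids overlaid, for visual quality control.
#'
#' @param img sprout-channel projection.
#' @param skel optional `skeleton_graph`.
#' @param puncta optional `puncta_set`.
#' @return A ggplot.
#' @export
plot_overlay <- function(img, skel = NULL, puncta = NULL) {
  px <- unclass(as.matrix(img))
  df <- tibble(y = rep(seq_len(nrow(px)), ncol(px)),
               x = rep(seq_len(ncol(px)), each = nrow(px)),
               intensity = as.numeric(px))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "green4") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(skel)) {
    p <- p + ggplot2::geom_point(data = skel$coords, size = 0.1,
                                 colour = "white")
    kept <- filter_endpoints_median_y(detect_endpoints(skel))
    if (nrow(kept)) {
      p <- p + ggplot2::geom_point(data = kept, colour = "cyan", size = 2,
                                   shape = 1)
    }
  }
  if (!is.null(puncta) && nrow(puncta)) {
    p <- p + ggplot2::geom_point(data = puncta, colour = "red", size = 1.5,
                                 shape = 3)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
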