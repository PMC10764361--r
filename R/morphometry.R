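#' Skeletonize a sprout mask
#'
#' Topology-preserving (Zhang-Suen) thinning of the binary sprout mask to a
#' one-pixel-wide, 8-connected skeleton, with endpoints (exactly one
#' skeleton neighbour) and junction clusters (8-adjacent groups of pixels
#' with three or more skeleton neighbours) annotated.
#'
#' @param mask a `binary_mask` (post blob-removal) or logical matrix.
#' @param labels optional [label_sprouts()] result; skeleton pixels are then
#'   assigned their sprout label.
#' @return An object of class `skeleton_graph`: list with `pixels` (logical
#'   matrix), `coords` (tibble `y`, `x`, `degree`, `label`), `endpoints`
#'   (tibble `y`, `x`, `label`), `junctions` (tibble `cluster`, `y`, `x`),
#'   `n_junction_clusters`, and the mask calibration.
#' @export
skeletonize_mask <- function(mask, labels = NULL) {
  m <- unclass(mask) == TRUE
  skel <- cpp_thin(m)
  ncount <- cpp_neighbor_count(skel)
  idx <- which(skel)
  ys <- (idx - 1) %% nrow(skel) + 1
  xs <- (idx - 1) %/% nrow(skel) + 1
  deg <- ncount[idx]
  lab <- if (!is.null(labels)) labels$labels[idx] else rep(NA_integer_, length(idx))
  coords <- tibble(y = ys, x = xs, degree = deg, label = lab)

  ep <- coords[coords$degree == 1, c("y", "x", "label")]

  jmask <- skel & ncount >= 3
  jlab <- cpp_label_components(jmask, 8L)
  jidx <- which(jmask)
  junctions <- tibble(cluster = jlab[jidx],
                      y = (jidx - 1) %% nrow(skel) + 1,
                      x = (jidx - 1) %/% nrow(skel) + 1)
  structure(list(pixels = skel, coords = coords, endpoints = ep,
                 junctions = junctions,
                 n_junction_clusters = if (nrow(junctions)) max(junctions$cluster) else 0L,
                 pixel_size_um = attr(mask, "pixel_size_um")),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d px, %d endpoint(s), %d junction cluster(s)\n",
              nrow(x$coords), nrow(x$endpoints), x$n_junction_clusters))
  invisible(x)
}

#' Skeleton endpoints
#'
#' All skeleton pixels with exactly one skeleton neighbour in the
#' 8-neighbourhood.
#'
#' @param skel a `skeleton_graph`.
#' @return A tibble with columns `y`, `x` (and `label` if sprouts were
#'   labelled).
#' @export
detect_endpoints <- function(skel) {
  stopifnot(inherits(skel, "skeleton_graph"))
  skel$endpoints
}

#' Median-y endpoint filter
#'
#' Retains exactly the endpoints whose y-coordinate is strictly greater
#' than the median y over all endpoints of the sample (the whole image).
#' Sprouts grow toward +y, so this discards the cluster of spurious
#' endpoints near the root monolayer and keeps tip-side endpoints. The
#' median of an even count is the mean of the two central values; ties at
#' the median are excluded.
#'
#' @param endpoints tibble with a `y` column (from [detect_endpoints()]), or
#'   a numeric vector of y-coordinates.
#' @return The retained endpoints (same type as the input).
#' @export
filter_endpoints_median_y <- function(endpoints) {
  if (is.numeric(endpoints)) {
    if (length(endpoints) == 0) return(endpoints)
    return(endpoints[endpoints > median(endpoints)])
  }
  if (nrow(endpoints) == 0) return(endpoints)
  endpoints[endpoints$y > median(endpoints$y), , drop = FALSE]
}

#' Branch-point (junction) count
#'
#' Number of junction clusters: groups of skeleton pixels with at least
#' three skeleton neighbours, merged by 8-adjacency and counted once per
#' group. In 2-D projections two crossing sprouts produce one junction
#' cluster, so crossings are counted as a single branch point (a known
#' over-count relative to true biological branching).
#'
#' @param skel a `skeleton_graph`.
#' @return Integer junction-cluster count.
#' @export
count_branch_points <- function(skel) {
  stopifnot(inherits(skel, "skeleton_graph"))
  as.integer(skel$n_junction_clusters)
}

#' Sprout morphometry feature panel
#'
#' Computes the per-sample morphology features from the mask, its skeleton
#' and the sprout labels: sprout area (foreground pixel count), total
#' length (skeleton pixel count, plus a diagonal-corrected variant),
#' tip-side endpoint count after the median-y filter, average sprout length
#' coefficient (mean y of retained endpoints), average sprout width
#' coefficient (area / skeleton length), branch-point count (junction
#' clusters) and the number of root-attached sprouts. Micrometre variants
#' are attached when the mask is calibrated.
#'
#' @param mask a `binary_mask`.
#' @param skel the `skeleton_graph` of `mask` (computed if omitted).
#' @param labels the [label_sprouts()] result for `mask` (computed if
#'   omitted).
#' @param sample_id,condition optional identifiers carried into the row.
#' @return A one-row tibble (class `morphometry_features`).
#' @export
compute_features <- function(mask, skel = NULL, labels = NULL,
                             sample_id = NA_character_,
                             condition = NA_character_) {
  if (is.null(labels)) labels <- label_sprouts(mask)
  if (is.null(skel)) skel <- skeletonize_mask(mask, labels)
  ps <- attr(mask, "pixel_size_um")

  area_px <- sum(unclass(mask) == TRUE)
  length_px <- nrow(skel$coords)
  length_corrected_px <- diagonal_corrected_length(skel)

  ep <- detect_endpoints(skel)
  kept <- filter_endpoints_median_y(ep)
  endpoint_count <- nrow(kept)
  avg_length_coeff_px <- if (endpoint_count > 0) mean(kept$y) else NA_real_
  avg_width_coeff_px <- if (length_px > 0) area_px / length_px else NA_real_
  branch_points <- count_branch_points(skel)
  n_sprouts <- if (nrow(labels$info)) sum(labels$info$root_attached) else 0L

  um <- function(v) if (is.null(ps)) NA_real_ else v * ps
  out <- tibble(
    sample_id = sample_id, condition = condition,
    area_px = area_px, area_um2 = if (is.null(ps)) NA_real_ else area_px * ps^2,
    length_px = length_px, length_um = um(length_px),
    length_corrected_px = length_corrected_px,
    endpoint_count = endpoint_count,
    avg_length_coeff_px = avg_length_coeff_px,
    avg_length_coeff_um = um(avg_length_coeff_px),
    avg_width_coeff_px = avg_width_coeff_px,
    avg_width_coeff_um = um(avg_width_coeff_px),
    branch_points = branch_points,
    n_sprouts = n_sprouts)
  class(out) <- c("morphometry_features", class(out))
  out
}

# Skeleton length with orthogonal steps counted 1 and diagonal steps sqrt(2),
# summed over adjacent skeleton pixel pairs (each pair once).
diagonal_corrected_length <- function(skel) {
  co <- skel$coords
  if (nrow(co) == 0) return(0)
  m <- skel$pixels
  nr <- nrow(m); nc <- ncol(m)
  shift_and <- function(dy, dx) {
    ys <- co$y + dy; xs <- co$x + dx
    ok <- ys >= 1 & ys <= nr & xs >= 1 & xs <= nc
    sum(m[cbind(ys[ok], xs[ok])])
  }
  # count each undirected pair once: neighbours at S, E, SE, SW
  orth <- shift_and(1, 0) + shift_and(0, 1)
  diag <- shift_and(1, 1) + shift_and(1, -1)
  orth + sqrt(2) * diag
}
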