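#' Specification for a synthetic sprout image
#'
#' Describes the generative model that emulates a cropped field of an
#' angiogenesis-on-a-chip well: tubular sprouts anchored on the root edge
#' (the strip adjoining the endothelial monolayer, at the top of the image)
#' growing toward +y, with optional bifurcations, bright LC3B-like puncta
#' placed at controlled arc-distances from the sprout tips, and optional
#' mCherry/GFP tandem-reporter channels. All randomness derives from
#' `seed`; the same spec and seed give bit-identical output.
#'
#' Tubes are rendered by stamping disks of radius width/2 along a centreline
#' polyline, so the truth length is the arc length of that centreline and
#' the rendered shape is a stadium whose medial axis coincides with it.
#'
#' @param n_sprouts sprouts per image.
#' @param length_mean_um,length_sd_um lognormal length distribution
#'   (micrometres), truncated to `length_range_um`.
#' @param length_range_um allowed length range (default 100-600 um).
#' @param width_mean_um,width_sd_um lognormal width distribution,
#'   truncated to `width_range_um`.
#' @param width_range_um allowed width range (default 10-40 um).
#' @param branch_rate mean bifurcation events per sprout (Poisson).
#' @param branch_events exact bifurcation events per sprout (a point-mass
#'   count distribution); `NULL` (default) draws from Poisson(`branch_rate`).
#' @param branch_min_sep_px minimum arc separation between bifurcation
#'   events on one sprout, in pixels.
#' @param branch_angle_deg range of branch angles off the parent direction.
#' @param curvature maximum angular deviation (radians) per 1-px step of
#'   the centreline random walk.
#' @param puncta_per_sprout mean puncta per sprout (Poisson, plus 1 so
#'   every sprout carries at least one punctum).
#' @param puncta_rel_shape `c(alpha, beta)` of the Beta distribution of
#'   relative punctum distance from the tip (fraction of sprout length).
#'   The default Beta(26, 66.91) has its mode at 0.275 and standard
#'   deviation ~0.046, mirroring the pronounced concentration of
#'   autophagosomes near (but not at) sprout tips: the 25-30%%-of-length
#'   bin clearly dominates its neighbours, so the modal bin is
#'   statistically identifiable from a 23-sprout sample.
#' @param puncta_rel_fixed if not `NULL`, a single relative distance used
#'   for every punctum (a point-mass placement distribution), overriding
#'   the Beta draw.
#' @param puncta_intensity_mean,puncta_intensity_sd lognormal total
#'   intensity per punctum.
#' @param puncta_sigma_px_range per-punctum Gaussian radius range (px).
#' @param foreground sprout tube intensity.
#' @param background constant background level added to all channels.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param shot_noise if `TRUE`, Poisson-resample pixel intensities.
#' @param pixel_size_um calibration (default 1 um/px).
#' @param image_size `c(ny, nx)` field size in pixels.
#' @param root_band_px root-band height in pixels.
#' @param dual_reporter render mCherry and GFP channels.
#' @param mcherry_gfp_ratio_range per-punctum mCherry:GFP intensity ratio
#'   range (uniform), used when `dual_reporter = TRUE`.
#' @param seed integer RNG seed.
#' @return A list of class `sprout_spec`.
#' @export
sprout_spec <- function(n_sprouts = 6,
                        length_mean_um = 300, length_sd_um = 120,
                        length_range_um = c(100, 600),
                        width_mean_um = 20, width_sd_um = 6,
                        width_range_um = c(10, 40),
                        branch_rate = 0.7,
                        branch_events = NULL,
                        branch_min_sep_px = 30,
                        branch_angle_deg = c(30, 60),
                        curvature = 0.03,
                        puncta_per_sprout = 7,
                        puncta_rel_shape = c(26, 66.91),
                        puncta_rel_fixed = NULL,
                        puncta_intensity_mean = 4000,
                        puncta_intensity_sd = 1200,
                        puncta_sigma_px_range = c(1.5, 3),
                        foreground = 180,
                        background = 20,
                        noise_sd = 4,
                        shot_noise = FALSE,
                        pixel_size_um = 1,
                        image_size = c(1000, 1000),
                        root_band_px = 20,
                        dual_reporter = FALSE,
                        mcherry_gfp_ratio_range = c(1.5, 3),
                        seed = 1L) {
  stopifnot(length_mean_um > 0, width_mean_um > 0, pixel_size_um > 0,
            all(image_size > 0), branch_rate >= 0, curvature >= 0,
            all(puncta_rel_shape > 0), puncta_intensity_mean > 0)
  spec <- as.list(environment())
  class(spec) <- "sprout_spec"
  spec
}

# lognormal draw with mean m and sd s on the natural scale, truncated.
rlnorm_ms <- function(n, m, s, range = NULL) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  x <- rlnorm(n, meanlog, sdlog)
  if (!is.null(range)) x <- pmin(pmax(x, range[1]), range[2])
  x
}

# Random-walk centreline of arc length len_px starting at (y0, x0), initial
# heading straight down (+y), per-step deviation bounded by `curvature`.
sample_polyline <- function(len_px, y0, x0, curvature, nx, theta0 = pi / 2) {
  n <- max(2, ceiling(len_px))
  ys <- numeric(n + 1); xs <- numeric(n + 1)
  ys[1] <- y0; xs[1] <- x0
  theta <- theta0  # angle from +x axis; pi/2 points to +y (down)
  for (i in seq_len(n)) {
    if (curvature > 0) theta <- theta + runif(1, -curvature, curvature)
    # keep heading within +/- 60 deg of straight down so growth stays +y
    theta <- pmin(pmax(theta, pi / 2 - pi / 3), pi / 2 + pi / 3)
    ys[i + 1] <- ys[i] + sin(theta)
    xs[i + 1] <- xs[i] + cos(theta)
    if (xs[i + 1] < 3) { xs[i + 1] <- 3; theta <- pi / 2 }
    if (xs[i + 1] > nx - 2) { xs[i + 1] <- nx - 2; theta <- pi / 2 }
  }
  # trim to requested arc length
  seg <- sqrt(diff(ys)^2 + diff(xs)^2)
  cum <- cumsum(seg)
  keep <- which(cum <= len_px)
  k <- if (length(keep)) max(keep) + 1 else 2
  cbind(y = ys[seq_len(k)], x = xs[seq_len(k)])
}

# Stamp disks of radius r (px) along a polyline into image `img` (max
# composition so overlapping tubes keep constant intensity).
stamp_tube <- function(img, poly, r, level) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- ceiling(r)
  off <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  off <- off[off$dy^2 + off$dx^2 <= r^2 + 1e-9, ]
  # disks every ~r/2 steps overlap heavily (scallop depth < 0.5 px);
  # enclosed holes are filled afterwards
  step <- max(1L, floor(r / 2))
  idx <- unique(c(seq(1, nrow(poly), by = step), nrow(poly)))
  yy <- floor(outer(poly[idx, 1], off$dy, "+") + 0.5)
  xx <- floor(outer(poly[idx, 2], off$dx, "+") + 0.5)
  ok <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
  ii <- cbind(yy[ok], xx[ok])
  img[ii] <- pmax(img[ii], level)
  img
}

# Fill enclosed background holes (4-components of background that do not
# reach the window border); rendered tubes are simply connected. The fill
# is restricted to the bounding box of the foreground, padded by one
# background ring so outside-background stays connected to the border.
fill_holes <- function(img, level) {
  fg <- which(img > 0, arr.ind = TRUE)
  if (nrow(fg) == 0) return(img)
  y0 <- max(1, min(fg[, 1]) - 1); y1 <- min(nrow(img), max(fg[, 1]) + 1)
  x0 <- max(1, min(fg[, 2]) - 1); x1 <- min(ncol(img), max(fg[, 2]) + 1)
  sub <- img[y0:y1, x0:x1, drop = FALSE]
  bg <- sub <= 0
  lab <- cpp_label_components(bg, 4L)
  border_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  hole <- bg & !(lab %in% setdiff(border_ids, 0L))
  dim(hole) <- dim(sub)
  sub[hole] <- level
  img[y0:y1, x0:x1] <- sub
  img
}

# Point on polyline at arc length s from the START; returns c(y, x).
point_at_arc <- function(poly, s) {
  seg <- sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)
  cum <- c(0, cumsum(seg))
  s <- pmin(pmax(s, 0), cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(i, length(seg))
  t <- (s - cum[i]) / seg[i]
  c(poly[i, 1] + t * (poly[i + 1, 1] - poly[i, 1]),
    poly[i, 2] + t * (poly[i + 1, 2] - poly[i, 2]))
}

arc_length <- function(poly) sum(sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2))

# A 2-D Gaussian spot patch of given total intensity, clipped to the image.
make_spot <- function(yc, xc, total, sigma, nr, nc) {
  ri <- ceiling(4 * sigma)
  ys <- max(1, round(yc) - ri):min(nr, round(yc) + ri)
  xs <- max(1, round(xc) - ri):min(nc, round(xc) + ri)
  g <- outer(ys - yc, xs - xc, function(dy, dx)
    exp(-(dy^2 + dx^2) / (2 * sigma^2)))
  list(ys = ys, xs = xs, g = g * (total / (2 * pi * sigma^2)))
}

# Add spot patches into an image in a single frame (one copy total).
apply_spots <- function(img, spots) {
  for (sp in spots) img[sp$ys, sp$xs] <- img[sp$ys, sp$xs] + sp$g
  img
}

#' Generate one synthetic multi-channel sprout image with ground truth
#'
#' Renders the sprout (membrane-marker) channel, the LC3B puncta channel
#' and, for dual-reporter specs, GFP and mCherry channels. Ground truth
#' (per-sprout centreline, length, width, branch points, tip coordinate;
#' per-punctum centroid, intensity and arc-distance from the tip) is
#' recorded before noise is added.
#'
#' @param spec a [sprout_spec()].
#' @return List with `channels` (named list of [projection2d]) and `truth`
#'   (list with tibbles `sprouts` and `puncta`, plus the centreline
#'   polylines).
#' @export
generate_sample <- function(spec) {
  stopifnot(inherits(spec, "sprout_spec"))
  withr::local_seed(spec$seed)
  ny <- spec$image_size[1]; nx <- spec$image_size[2]
  ps <- spec$pixel_size_um
  sprout_ch <- matrix(0, ny, nx)
  spots_lc3b <- list(); spots_gfp <- list(); spots_mch <- list()

  n <- spec$n_sprouts
  # spread roots across x with jitter, away from borders
  slots <- seq(0.5, n - 0.5) / n
  x0s <- round(nx * (0.06 + 0.88 * slots) + runif(n, -nx * 0.015, nx * 0.015))

  sp_acc <- list(); pn_acc <- list(); polylines <- list()
  branch_polys <- list()
  for (s in seq_len(n)) {
    ok <- FALSE
    for (try in 1:100) {
      len_um <- rlnorm_ms(1, spec$length_mean_um, spec$length_sd_um,
                          spec$length_range_um)
      wid_um <- rlnorm_ms(1, spec$width_mean_um, spec$width_sd_um,
                          spec$width_range_um)
      len_px <- len_um / ps
      r <- (wid_um / ps) / 2
      if (r + len_px + r < ny - 2) { ok <- TRUE; break }
    }
    if (!ok) abort("Spec cannot fit a sprout in the image after 100 retries.")
    poly <- sample_polyline(len_px, y0 = r + 1, x0 = x0s[s],
                            curvature = spec$curvature, nx = nx)
    len_px_true <- arc_length(poly)
    layer <- stamp_tube(matrix(0, ny, nx), poly, r, spec$foreground)

    # bifurcation events, kept well separated along the parent
    k <- spec$branch_events %||% rpois(1, spec$branch_rate)
    bps <- matrix(numeric(0), 0, 2)
    if (k > 0) {
      pos <- sort(runif(k, 0.25, 0.75)) * len_px_true
      if (!is.null(spec$branch_events)) {
        # exact event count requested: resample until positions separate
        for (try in 1:100) {
          if (k == 1 || all(diff(pos) > spec$branch_min_sep_px)) break
          pos <- sort(runif(k, 0.25, 0.75)) * len_px_true
        }
      }
      pos <- pos[c(TRUE, diff(pos) > spec$branch_min_sep_px)]
      # exact-count mode realises *well-separated* bifurcations: sides
      # alternate and each side uses one angle, so same-side branch tubes
      # are parallel and cannot merge into a single junction
      exact <- !is.null(spec$branch_events)
      side0 <- sample(c(-1, 1), 1)
      side_angle <- runif(2, spec$branch_angle_deg[1], spec$branch_angle_deg[2])
      for (bi in seq_along(pos)) {
        p <- pos[bi]
        bp <- point_at_arc(poly, p)
        side <- if (exact) side0 * (-1)^(bi - 1) else sample(c(-1, 1), 1)
        ang <- if (exact) {
          side_angle[1 + (bi - 1) %% 2]
        } else {
          runif(1, spec$branch_angle_deg[1], spec$branch_angle_deg[2])
        }
        blen <- max(2.5 * 2 * r + 20, 0.4 * (len_px_true - p))
        blen <- min(blen, 0.9 * (ny - bp[1]))
        theta0 <- pi / 2 + side * ang * pi / 180
        bpoly <- sample_polyline(blen, bp[1], bp[2], spec$curvature / 2, nx,
                                 theta0 = theta0)
        layer <- stamp_tube(layer, bpoly, 0.8 * r, spec$foreground)
        branch_polys[[length(branch_polys) + 1]] <- bpoly
        bps <- rbind(bps, bp)
      }
    }
    layer <- fill_holes(layer, spec$foreground)
    lay_idx <- which(layer > 0)
    area_px_true <- length(lay_idx)
    sprout_ch[lay_idx] <- pmax(sprout_ch[lay_idx], layer[lay_idx])
    tip <- poly[nrow(poly), ]

    # puncta at Beta-distributed relative distances from the tip
    npun <- 1 + rpois(1, max(spec$puncta_per_sprout - 1, 0))
    rel <- if (!is.null(spec$puncta_rel_fixed)) {
      rep(spec$puncta_rel_fixed, npun)
    } else {
      rbeta(npun, spec$puncta_rel_shape[1], spec$puncta_rel_shape[2])
    }
    arc_from_tip <- rel * len_px_true
    ints <- rlnorm_ms(npun, spec$puncta_intensity_mean,
                      spec$puncta_intensity_sd)
    sig <- runif(npun, spec$puncta_sigma_px_range[1],
                 spec$puncta_sigma_px_range[2])
    for (j in seq_len(npun)) {
      pc <- point_at_arc(poly, len_px_true - arc_from_tip[j])
      # small lateral jitter inside the tube
      jit <- runif(2, -0.3 * r, 0.3 * r)
      yc <- pc[1] + jit[1]; xc <- pc[2] + jit[2]
      spots_lc3b[[length(spots_lc3b) + 1]] <-
        make_spot(yc, xc, ints[j], sig[j], ny, nx)
      if (spec$dual_reporter) {
        ratio <- runif(1, spec$mcherry_gfp_ratio_range[1],
                       spec$mcherry_gfp_ratio_range[2])
        gfp_int <- ints[j] / (1 + ratio)
        mch_int <- ints[j] * ratio / (1 + ratio)
        spots_gfp[[length(spots_gfp) + 1]] <-
          make_spot(yc, xc, gfp_int, sig[j], ny, nx)
        spots_mch[[length(spots_mch) + 1]] <-
          make_spot(yc, xc, mch_int, sig[j], ny, nx)
      }
      pn_acc[[length(pn_acc) + 1]] <- c(
        sprout = s, y = yc, x = xc, total_intensity = ints[j],
        sigma_px = sig[j], arc_dist_um = arc_from_tip[j] * ps,
        rel_dist = rel[j])
    }
    # width_coeff_um: the analytic width coefficient of the rendered shape
    # (true area / true centreline length) - the quantity the area/length
    # estimator targets; exceeds the nominal tube width by ~pi*r^2/L from
    # the rounded end caps.
    sp_acc[[s]] <- c(
      sprout = s, length_um = len_px_true * ps, width_um = wid_um,
      area_px = area_px_true,
      width_coeff_um = area_px_true * ps^2 / (len_px_true * ps),
      n_branches = nrow(bps), tip_y = tip[1], tip_x = tip[2],
      root_x = x0s[s])
    polylines[[s]] <- poly
  }
  sprouts_tbl <- as_tibble(as.data.frame(do.call(rbind, sp_acc)))
  puncta_tbl <- if (length(pn_acc)) {
    as_tibble(as.data.frame(do.call(rbind, pn_acc)))
  } else tibble()

  lc3b_ch <- apply_spots(matrix(0, ny, nx), spots_lc3b)
  gfp_ch <- if (spec$dual_reporter) apply_spots(matrix(0, ny, nx), spots_gfp) else NULL
  mch_ch <- if (spec$dual_reporter) apply_spots(matrix(0, ny, nx), spots_mch) else NULL

  add_noise <- function(img) {
    img <- img + spec$background
    if (spec$shot_noise) img <- matrix(rpois(length(img), img), nrow(img))
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sd),
                          nrow(img))
    }
    pmax(img, 0)
  }
  channels <- list(
    sprout = projection2d(add_noise(sprout_ch), ps, "sprout"),
    lc3b = projection2d(add_noise(lc3b_ch), ps, "lc3b"))
  if (spec$dual_reporter) {
    channels$gfp <- projection2d(add_noise(gfp_ch), ps, "gfp")
    channels$mcherry <- projection2d(add_noise(mch_ch), ps, "mcherry")
  }
  list(channels = channels,
       truth = list(sprouts = sprouts_tbl,
                    puncta = puncta_tbl,
                    polylines = polylines,
                    branch_polylines = branch_polys,
                    spec = spec))
}

#' Generate a multi-condition synthetic dataset
#'
#' Applies per-condition multiplicative effects to the base spec's
#' distribution parameters and draws `n_samples` independent images per
#' condition. Recognised effect names: `length`, `width`, `branching`,
#' `puncta_intensity`. Sample seeds are derived deterministically from
#' `seed` and recorded in the manifest.
#'
#' @param base a [sprout_spec()].
#' @param effects named list of named multiplier vectors, e.g.
#'   `list(control = c(), inhibitor = c(length = 0.5))`.
#' @param n_samples samples (images) per condition.
#' @param seed master seed.
#' @return List with `samples` (list of [generate_sample()] results) and
#'   `manifest` (tibble `sample_id`, `condition`, `seed`).
#' @export
generate_condition_set <- function(base, effects, n_samples, seed = 1L) {
  stopifnot(inherits(base, "sprout_spec"), n_samples >= 1)
  conds <- names(effects)
  if (is.null(conds) || any(!nzchar(conds))) {
    abort("`effects` must be a named list of conditions.")
  }
  manifest <- list(); samples <- list()
  i <- 0L
  for (ci in seq_along(conds)) {
    eff <- effects[[ci]]
    if (any(eff <= 0)) abort("Effect multipliers must be > 0.")
    spec <- base
    if ("length" %in% names(eff)) {
      spec$length_mean_um <- spec$length_mean_um * eff[["length"]]
      spec$length_range_um <- spec$length_range_um * eff[["length"]]
    }
    if ("width" %in% names(eff)) {
      spec$width_mean_um <- spec$width_mean_um * eff[["width"]]
      spec$width_range_um <- spec$width_range_um * eff[["width"]]
    }
    if ("branching" %in% names(eff)) {
      spec$branch_rate <- spec$branch_rate * eff[["branching"]]
    }
    if ("puncta_intensity" %in% names(eff)) {
      spec$puncta_intensity_mean <-
        spec$puncta_intensity_mean * eff[["puncta_intensity"]]
    }
    for (rep in seq_len(n_samples)) {
      i <- i + 1L
      spec_i <- spec
      spec_i$seed <- (seed * 10007L + i * 131L) %% .Machine$integer.max
      samples[[i]] <- generate_sample(spec_i)
      manifest[[i]] <- tibble(sample_id = sprintf("s%03d", i),
                              condition = conds[ci], seed = spec_i$seed)
    }
  }
  list(samples = samples, manifest = bind_rows(manifest))
}
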