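# Independent brute-force oracles used across the suite. All are plain R
# loops, deliberately naive, and share no code with the implementation.

# 8-neighbour count of every pixel, per-pixel loop.
oracle_neighbor_count <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    cnt <- 0L
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      yy <- y + dy; xx <- x + dx
      if (yy >= 1 && yy <= nr && xx >= 1 && xx <= nc && m[yy, xx]) cnt <- cnt + 1L
    }
    out[y, x] <- cnt
  }
  out
}

# Endpoints (degree 1) of a skeleton, via the neighbour-count oracle.
oracle_endpoints <- function(skel_px) {
  nc8 <- oracle_neighbor_count(skel_px)
  which(skel_px & nc8 == 1, arr.ind = TRUE)
}

# Junction clusters: pixels with >= 3 neighbours, grouped by 8-adjacency
# via naive flood fill; returns the number of clusters.
oracle_junction_clusters <- function(skel_px) {
  nc8 <- oracle_neighbor_count(skel_px)
  jn <- skel_px & nc8 >= 3
  oracle_n_components(jn, connectivity = 8)
}

# Naive flood-fill component labelling.
oracle_label <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 8) {
    cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1), dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dy = c(-1, 1, 0, 0), dx = c(0, 0, -1, 1))
  }
  cur <- 0L
  for (y0 in seq_len(nr)) for (x0 in seq_len(nc)) {
    if (!m[y0, x0] || lab[y0, x0] != 0) next
    cur <- cur + 1L
    queue <- list(c(y0, x0)); lab[y0, x0] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        yy <- p[1] + nbr[k, 1]; xx <- p[2] + nbr[k, 2]
        if (yy >= 1 && yy <= nr && xx >= 1 && xx <= nc &&
            m[yy, xx] && lab[yy, xx] == 0) {
          lab[yy, xx] <- cur
          queue[[length(queue) + 1]] <- c(yy, xx)
        }
      }
    }
  }
  lab
}

oracle_n_components <- function(m, connectivity = 8) {
  max(oracle_label(m, connectivity))
}

# Sort-based median-y filter: retain y strictly greater than the median
# (even count: mean of the two central order statistics).
oracle_median_filter <- function(ys) {
  if (length(ys) == 0) return(ys)
  s <- sort(ys)
  n <- length(s)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  ys[ys > med]
}

# Per-pixel distance binning oracle: for each puncta pixel, Euclidean
# distance to the endpoint in um, bin floor(d / w); returns bin sums.
oracle_radial_bins <- function(pix, endpoint, bin_width_um, ps,
                               weights = pix$intensity) {
  if (nrow(pix) == 0) return(numeric(0))
  sums <- list()
  for (i in seq_len(nrow(pix))) {
    d <- sqrt((pix$y[i] - endpoint[["y"]])^2 + (pix$x[i] - endpoint[["x"]])^2) * ps
    b <- floor(d / bin_width_um)
    key <- as.character(b)
    sums[[key]] <- (if (is.null(sums[[key]])) 0 else sums[[key]]) + weights[i]
  }
  mx <- max(as.integer(names(sums)))
  out <- numeric(mx + 1)
  for (key in names(sums)) out[as.integer(key) + 1] <- sums[[key]]
  out
}

# Random skeleton-like structures: union of a few random walks, thinned by
# the package (the detection equivalence is then checked on the thinned
# pixels with the oracles above).
random_stroke_mask <- function(seed, ny = 80, nx = 80, n_strokes = 4) {
  set.seed(seed)
  m <- matrix(FALSE, ny, nx)
  for (s in seq_len(n_strokes)) {
    y <- runif(1, 10, ny - 10); x <- runif(1, 10, nx - 10)
    th <- runif(1, 0, 2 * pi)
    for (i in seq_len(round(runif(1, 15, 40)))) {
      th <- th + runif(1, -0.3, 0.3)
      y <- min(max(y + sin(th), 2), ny - 1)
      x <- min(max(x + cos(th), 2), nx - 1)
      m[round(y), round(x)] <- TRUE
      # widen to 3 px so thinning has work to do
      m[round(y) + (-1:1), round(x)] <- TRUE
    }
  }
  m
}

# A small straight-tube sample spec used in several tests.
straight_tube_spec <- function(seed, length_range = c(100, 600),
                               width_range = c(10, 40),
                               image_size = c(660, 200)) {
  sprout_spec(n_sprouts = 1,
              length_mean_um = mean(length_range), length_sd_um = 150,
              length_range_um = length_range,
              width_mean_um = 22, width_sd_um = 9,
              width_range_um = width_range,
              branch_events = 0, curvature = 0,
              noise_sd = 0, background = 0, puncta_per_sprout = 1,
              image_size = image_size, seed = seed)
}

noise_free_cfg <- function() {
  preprocess_config(gaussian_sigma_px = 0, threshold_mode = "fixed",
                    threshold_value = 90, min_blob_area_px = 50)
}
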