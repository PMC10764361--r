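make_spot_image <- function(centers, total = 100, sigma = 1.5,
                            ny = 80, nx = 80, bg = 10) {
  px <- matrix(bg, ny, nx)
  for (i in seq_len(nrow(centers))) {
    yc <- centers[i, 1]; xc <- centers[i, 2]
    ys <- max(1, yc - 8):min(ny, yc + 8)
    xs <- max(1, xc - 8):min(nx, xc + 8)
    g <- outer(ys - yc, xs - xc, function(dy, dx)
      exp(-(dy^2 + dx^2) / (2 * sigma^2)))
    px[ys, xs] <- px[ys, xs] + g * total / (2 * pi * sigma^2)
  }
  projection2d(px, pixel_size_um = 1, channel = "lc3b")
}

test_that("puncta detection finds spots, applies the area filter, localises centroids", {
  img <- make_spot_image(cbind(40, 40), total = 5000, sigma = 2)
  p <- detect_puncta(img, threshold = 50)
  expect_equal(nrow(p), 1)
  expect_lt(abs(p$y - 40), 1); expect_lt(abs(p$x - 40), 1)

  # single-pixel spot removed by min_area
  px <- matrix(0, 30, 30); px[15, 15] <- 500
  p2 <- detect_puncta(projection2d(px, 1), threshold = 50, min_area_px = 4)
  expect_equal(nrow(p2), 0)

  # 20 spots at known positions -> 20 centroids within 1 px
  set.seed(21)
  centers <- cbind(sample(15:185, 20), sample(15:185, 20))
  while (min(dist(centers)) < 14) {
    centers <- cbind(sample(15:185, 20), sample(15:185, 20))
  }
  img3 <- make_spot_image(centers, total = 4000, sigma = 2, ny = 200, nx = 200)
  p3 <- detect_puncta(img3, threshold = 60)
  expect_equal(nrow(p3), 20)
  found <- as.matrix(p3[, c("y", "x")])
  for (i in seq_len(20)) {
    d <- sqrt((found[, 1] - centers[i, 1])^2 + (found[, 2] - centers[i, 2])^2)
    expect_lt(min(d), 1)
  }
})

test_that("centre of gravity is the intensity-weighted pixel mean", {
  # two equal puncta at (30,20) and (30,40) -> cog x = 30
  img <- make_spot_image(rbind(c(30, 20), c(30, 40)), total = 3000, bg = 0)
  p <- detect_puncta(img, threshold = 30)
  cog <- puncta_center_of_gravity(p)
  expect_lt(abs(cog[["x"]] - 30), 0.2)
  expect_lt(abs(cog[["y"]] - 30), 0.2)

  set.seed(5)
  for (rep in 1:10) {
    px <- matrix(round(runif(400, 0, 200)), 20, 20)
    pr <- projection2d(px, 1)
    p <- detect_puncta(pr, threshold = 100, min_area_px = 1, max_area_px = 400)
    pix <- attr(p, "pixel_data")
    if (nrow(pix) == 0) next
    cog <- puncta_center_of_gravity(p)
    expect_equal(cog[["y"]], sum(pix$y * pix$intensity) / sum(pix$intensity))
    expect_equal(cog[["x"]], sum(pix$x * pix$intensity) / sum(pix$intensity))
  }
})

test_that("radial binning matches the definition on a single punctum", {
  # all pixels of one punctum at distance ~23 um -> bin [20,30) holds all
  px <- matrix(0, 60, 60)
  px[10, 33] <- 100  # distance 23 from (10,10)
  p <- detect_puncta(projection2d(px, 1), threshold = 10, min_area_px = 1)
  pr <- radial_profile(p, c(y = 10, x = 10), bin_width_um = 10)
  expect_equal(pr$value[pr$bin_low_um == 20], 100)
  expect_equal(sum(pr$value), 100)

  # no puncta -> all-zero profile
  p0 <- detect_puncta(projection2d(matrix(0, 20, 20), 1), threshold = 10)
  pr0 <- radial_profile(p0, c(y = 1, x = 1))
  expect_true(all(pr0$value == 0))
})

test_that("per-bin sums equal the brute-force per-pixel oracle with conserved totals", {
  set.seed(13)
  for (rep in 1:20) {
    px <- matrix(0L, 70, 70)
    n_spots <- sample(3:8, 1)
    for (i in seq_len(n_spots)) {
      yc <- sample(8:62, 1); xc <- sample(8:62, 1)
      px[yc + (-2:2), xc + (-2:2)] <- sample.int(300, 25, replace = TRUE)
    }
    pr2d <- projection2d(px, pixel_size_um = 1.5)
    p <- detect_puncta(pr2d, threshold = 40, min_area_px = 1, max_area_px = 500)
    pix <- attr(p, "pixel_data")
    if (nrow(pix) == 0) next
    ep <- c(y = sample(1:70, 1), x = sample(1:70, 1))
    prof <- radial_profile(p, ep, bin_width_um = 10)
    ob <- oracle_radial_bins(pix, ep, 10, 1.5)
    expect_equal(prof$value, c(ob, rep(0, nrow(prof) - length(ob))))
    expect_equal(sum(prof$value), sum(pix$intensity))
    # pixel-count metric against counting oracle
    prof_n <- radial_profile(p, ep, bin_width_um = 10, metric = "pixel_count")
    ob_n <- oracle_radial_bins(pix, ep, 10, 1.5, weights = rep(1, nrow(pix)))
    expect_equal(prof_n$value, c(ob_n, rep(0, nrow(prof_n) - length(ob_n))))
    expect_equal(sum(prof_n$value), nrow(pix))
  }
})

test_that("relative re-binning conserves signal and lands known pixels in known bins", {
  # pixel at 27 um on a 100 um sprout, 5% bins -> bin [25,30)
  px <- matrix(0, 40, 40); px[10, 37] <- 55  # distance 27 from (10,10)
  p <- detect_puncta(projection2d(px, 1), threshold = 10, min_area_px = 1)
  prof <- radial_profile(p, c(y = 10, x = 10), bin_width_um = 10)
  rel <- to_relative_profile(prof, sprout_length_um = 100, bin_percent = 5)
  expect_equal(rel$value[rel$bin_low_pct == 25], 55)
  expect_equal(sum(rel$value), sum(prof$value))
  # all signal at the endpoint -> bin [0,5)
  px2 <- matrix(0, 30, 30); px2[10, 10:11] <- c(60, 40)
  p2 <- detect_puncta(projection2d(px2, 1), threshold = 10, min_area_px = 1)
  prof2 <- radial_profile(p2, c(y = 10, x = 10))
  rel2 <- to_relative_profile(prof2, 200, 5)
  expect_equal(rel2$value[1], 100)
  expect_error(to_relative_profile(prof2, 0), "> 0")

  set.seed(31)
  for (rep in 1:10) {
    px <- matrix(sample.int(200, 900, replace = TRUE), 30, 30)
    p <- detect_puncta(projection2d(px, 1), threshold = 120, min_area_px = 1)
    prof <- radial_profile(p, c(y = 3, x = 3))
    L <- runif(1, 30, 120)
    expect_equal(sum(to_relative_profile(prof, L)$value), sum(prof$value))
  }
})

test_that("profile aggregation matches direct recomputation for sum and mean±SEM", {
  mk <- function(vals) {
    out <- tibble::tibble(bin_low_um = (seq_along(vals) - 1) * 10,
                          bin_high_um = seq_along(vals) * 10,
                          bin_mid_um = (seq_along(vals) - 0.5) * 10,
                          value = vals)
    attr(out, "mode") <- "absolute_um"; attr(out, "metric") <- "intensity_sum"
    attr(out, "bin_width") <- 10
    class(out) <- c("radial_profile", class(out))
    out
  }
  a <- mk(c(0, 10)); b <- mk(c(0, 20))
  s <- aggregate_profiles(list(a, a), "sum")
  expect_equal(s$value, c(0, 20))
  ms <- aggregate_profiles(list(a, b), "mean_sem")
  expect_equal(ms$mean, c(0, 15))
  expect_equal(ms$sem, c(0, 5))

  set.seed(8)
  profs <- lapply(1:6, function(i) mk(round(runif(sample(3:6, 1), 0, 50))))
  agg <- aggregate_profiles(profs, "mean_sem")
  nb <- nrow(agg)
  mat <- sapply(profs, function(p) c(p$value, rep(0, nb - nrow(p))))
  expect_equal(agg$mean, rowMeans(mat))
  expect_equal(agg$sem, apply(mat, 1, sd) / sqrt(6))
  # mixed bin definitions are rejected
  bad <- mk(c(1, 2)); attr(bad, "bin_width") <- 5
  expect_error(aggregate_profiles(list(a, bad)), "share")
})

test_that("puncta-positive sprout counting uses root-attached labels only", {
  m <- matrix(FALSE, 60, 60)
  m[1:40, 5:10] <- TRUE    # sprout 1, root-attached
  m[1:30, 25:30] <- TRUE   # sprout 2, root-attached
  m[45:55, 45:50] <- TRUE  # floating blob
  lb <- label_sprouts(m, root_band_px = 10)
  px <- matrix(0, 60, 60)
  px[20 + (-1:1), 7 + (-1:1)] <- 300   # punctum on sprout 1
  px[50 + (-1:1), 47 + (-1:1)] <- 300  # punctum on the floating blob
  p <- detect_puncta(projection2d(px, 1), lb, threshold = 50, min_area_px = 1)
  expect_equal(count_puncta_positive_sprouts(p, lb), 1)
  p_none <- detect_puncta(projection2d(matrix(0, 60, 60), 1), lb, threshold = 50)
  expect_equal(count_puncta_positive_sprouts(p_none, lb), 0)
})

test_that("dual-reporter ratio follows planted signals and scales linearly", {
  region <- matrix(TRUE, 40, 40)
  mc <- matrix(0, 40, 40); gf <- matrix(0, 40, 40)
  mc[10:12, 10:12] <- 100  # sum 900
  gf[20:22, 20:22] <- 50   # sum 450
  r <- dual_reporter_ratio(projection2d(mc, 1), projection2d(gf, 1), region,
                           threshold_mcherry = 10, threshold_gfp = 10)
  expect_equal(r$mcherry_signal, 900)
  expect_equal(r$gfp_signal, 450)
  expect_equal(r$ratio, 2)
  # identical channels give ratio exactly 1
  r1 <- dual_reporter_ratio(projection2d(mc, 1), projection2d(mc, 1), region,
                            threshold_mcherry = 10, threshold_gfp = 10)
  expect_equal(r1$ratio, 1)
  # scaling mCherry by s scales the ratio by s exactly
  for (sc in c(0.5, 3, 7.25)) {
    rs <- dual_reporter_ratio(projection2d(mc * sc, 1), projection2d(gf, 1),
                              region, threshold_mcherry = 10, threshold_gfp = 10)
    expect_equal(rs$ratio, 2 * sc)
  }
  # zero GFP -> missing ratio
  r0 <- dual_reporter_ratio(projection2d(mc, 1),
                            projection2d(matrix(0, 40, 40), 1), region,
                            threshold_mcherry = 10, threshold_gfp = 10)
  expect_true(is.na(r0$ratio))
})

test_that("basement and leading region masks take opposite ends of each sprout", {
  m <- matrix(FALSE, 100, 30)
  m[1:80, 10:15] <- TRUE
  lb <- label_sprouts(m, root_band_px = 10)
  rg <- region_masks(lb, fraction = 0.25)
  ys_b <- which(rg$basement, arr.ind = TRUE)[, 1]
  ys_l <- which(rg$leading, arr.ind = TRUE)[, 1]
  expect_lte(max(ys_b), 20)
  expect_gte(min(ys_l), 61)
  expect_false(any(rg$basement & rg$leading))
})
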