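test_that("identical spec and seed give bit-identical images and truth", {
  spec <- sprout_spec(n_sprouts = 3, image_size = c(400, 300), seed = 77)
  a <- generate_sample(spec)
  b <- generate_sample(spec)
  expect_identical(unclass(a$channels$sprout), unclass(b$channels$sprout))
  expect_identical(unclass(a$channels$lc3b), unclass(b$channels$lc3b))
  expect_identical(a$truth$sprouts, b$truth$sprouts)
  expect_identical(a$truth$puncta, b$truth$puncta)
  c <- generate_sample(sprout_spec(n_sprouts = 3, image_size = c(400, 300),
                                   seed = 78))
  expect_false(identical(unclass(a$channels$sprout), unclass(c$channels$sprout)))
})

test_that("a zero-curvature, zero-noise, unbranched spec draws one straight bar", {
  spec <- sprout_spec(n_sprouts = 1, length_range_um = c(300, 300),
                      length_mean_um = 300, length_sd_um = 1e-9,
                      width_range_um = c(20, 20), width_mean_um = 20,
                      width_sd_um = 1e-9, branch_events = 0, curvature = 0,
                      noise_sd = 0, background = 0, image_size = c(400, 100),
                      seed = 4)
  s <- generate_sample(spec)
  tr <- s$truth$sprouts
  expect_equal(tr$length_um, 300, tolerance = 0.01)
  expect_equal(tr$width_um, 20)
  expect_equal(tr$n_branches, 0)
  # constant x along the centreline
  poly <- s$truth$polylines[[1]]
  expect_equal(max(poly[, 2]) - min(poly[, 2]), 0)
  # mask touches the root edge
  expect_true(any(unclass(s$channels$sprout)[1, ] > 0))
})

test_that("point-mass puncta placement yields exact arc distances", {
  spec <- sprout_spec(n_sprouts = 1, length_range_um = c(400, 400),
                      length_mean_um = 400, length_sd_um = 1e-9,
                      branch_events = 0, curvature = 0, noise_sd = 0,
                      puncta_per_sprout = 10, puncta_rel_fixed = 0.27,
                      image_size = c(500, 120), seed = 10)
  s <- generate_sample(spec)
  expect_true(all(abs(s$truth$puncta$rel_dist - 0.27) < 1e-12))
  expect_true(all(abs(s$truth$puncta$arc_dist_um -
                        0.27 * s$truth$sprouts$length_um) < 1e-9))
})

test_that("rendered punctum intensity matches the specified total within 1%", {
  spec <- sprout_spec(n_sprouts = 2, noise_sd = 0, background = 0,
                      image_size = c(500, 300), seed = 12)
  s <- generate_sample(spec)
  lc3b <- unclass(s$channels$lc3b)
  expect_lt(abs(sum(lc3b) - sum(s$truth$puncta$total_intensity)) /
              sum(s$truth$puncta$total_intensity), 0.01)
})

test_that("noise-free rendering measures back to truth within stated bands", {
  for (seed in c(1, 6, 14)) {
    s <- generate_sample(straight_tube_spec(seed))
    f <- measure_sample(s$channels$sprout, noise_free_cfg())
    tr <- s$truth$sprouts
    expect_lt(abs(f$length_px - tr$length_um) / tr$length_um, 0.05)
    expect_lt(abs(f$avg_width_coeff_px - tr$width_coeff_um) / tr$width_coeff_um,
              0.10)
    expect_equal(f$branch_points, 0)
    expect_equal(f$endpoint_count, 1)
  }
  # slender tubes also recover the nominal tube width within 10%
  spec <- straight_tube_spec(3, length_range = c(400, 600),
                             width_range = c(10, 20))
  s <- generate_sample(spec)
  f <- measure_sample(s$channels$sprout, noise_free_cfg())
  expect_lt(abs(f$avg_width_coeff_px - s$truth$sprouts$width_um) /
              s$truth$sprouts$width_um, 0.10)
})

test_that("condition sets scale distribution parameters and are reproducible", {
  base <- sprout_spec(n_sprouts = 2, image_size = c(400, 250),
                      length_mean_um = 200, length_sd_um = 60,
                      length_range_um = c(100, 350))
  effects <- list(control = c(), drug = c(length = 0.5))
  ds <- generate_condition_set(base, effects, n_samples = 3, seed = 5)
  expect_equal(nrow(ds$manifest), 6)
  expect_equal(ds$manifest$condition, rep(c("control", "drug"), each = 3))
  truth_len <- vapply(ds$samples, function(s) mean(s$truth$sprouts$length_um),
                      numeric(1))
  expect_gt(mean(truth_len[1:3]), mean(truth_len[4:6]))
  ds2 <- generate_condition_set(base, effects, n_samples = 3, seed = 5)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(unclass(ds$samples[[4]]$channels$sprout),
                   unclass(ds2$samples[[4]]$channels$sprout))
  expect_error(generate_condition_set(base, list(a = c(length = -1)), 2),
               "> 0")
  expect_error(generate_condition_set(base, list(c(length = 1)), 2), "named")
})

test_that("dual-reporter channels partition punctum intensity by the drawn ratio", {
  spec <- sprout_spec(n_sprouts = 1, dual_reporter = TRUE, noise_sd = 0,
                      background = 0, image_size = c(400, 150),
                      branch_events = 0, seed = 9)
  s <- generate_sample(spec)
  tot <- sum(s$truth$puncta$total_intensity)
  gfp <- sum(unclass(s$channels$gfp)); mch <- sum(unclass(s$channels$mcherry))
  expect_lt(abs((gfp + mch) - tot) / tot, 0.01)
  # mCherry dominates GFP within the configured ratio range
  expect_gt(mch / gfp, spec$mcherry_gfp_ratio_range[1] * 0.8)
  expect_lt(mch / gfp, spec$mcherry_gfp_ratio_range[2] * 1.2)
})
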