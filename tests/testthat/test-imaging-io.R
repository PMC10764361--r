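test_that("max projection takes the per-pixel maximum over z", {
  vox <- array(0, dim = c(1, 2, 2, 2))
  vox[1, 1, , ] <- matrix(c(3, 0, 5, 1), 2, 2)
  vox[1, 2, , ] <- matrix(c(7, 0, 2, 4), 2, 2)
  st <- image_stack(vox, "cd31", pixel_size_um = 1.24)
  pr <- max_project(st, "cd31")
  expect_equal(unclass(pr)[, ], matrix(c(7, 0, 5, 4), 2, 2),
               ignore_attr = TRUE)
  expect_equal(pixel_size(pr), 1.24)
  # single z-plane: projection is the identity
  st1 <- image_stack(array(1:12, dim = c(1, 1, 3, 4)))
  expect_equal(as.vector(max_project(st1, 1)), as.vector(1:12))
})

test_that("unknown channels are rejected with the available list", {
  st <- image_stack(array(0, dim = c(2, 1, 4, 4)), c("cd31", "lc3b"))
  expect_error(max_project(st, "dapi"), "cd31, lc3b")
  expect_error(max_project(st, 5L), "2 channels")
})

test_that("cropping respects bounds, preserves calibration, is reusable", {
  img <- projection2d(matrix(seq_len(100 * 100), 100, 100), 0.5)
  full <- crop_projection(img, c(1, 100, 1, 100))
  expect_equal(unclass(full), unclass(img), ignore_attr = TRUE)
  sub <- crop_projection(img, c(1, 10, 1, 10))
  expect_equal(dim(sub), c(10, 10))
  expect_equal(pixel_size(sub), 0.5)
  img2 <- projection2d(matrix(0, 100, 100), 0.5)
  expect_equal(dim(crop_projection(img2, c(1, 10, 1, 10))), dim(sub))
  expect_error(crop_projection(img, c(50, 120, 1, 10)), "bounds")
})

test_that("TIFF round-trip reproduces integer voxels and calibration", {
  px <- matrix(sample.int(65535, 64 * 48, replace = TRUE) - 1L, 64, 48)
  img <- projection2d(px, pixel_size_um = 1.24, channel = "cd31")
  path <- withr::local_tempfile(fileext = ".tif")
  write_projection(img, path)
  st <- load_image(path)
  expect_equal(dim(st$voxels), c(1, 1, 64, 48))
  expect_equal(st$voxels[1, 1, , ], px, ignore_attr = TRUE)
  expect_equal(st$pixel_size_um, 1.24)
  expect_equal(st$channel_names, "cd31")
  # override wins over the sidecar
  st2 <- load_image(path, pixel_size_override = 2)
  expect_equal(st2$pixel_size_um, 2)
})

test_that("2-D single-channel TIFF loads as a (1,1,y,x) stack", {
  px <- matrix(sample.int(256, 32 * 32, replace = TRUE) - 1L, 32, 32)
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(px / 255, path, bits.per.sample = 8)
  st <- load_image(path)
  expect_equal(dim(st$voxels), c(1, 1, 32, 32))
  expect_equal(st$voxels[1, 1, , ], px, ignore_attr = TRUE)
})

test_that("uncalibrated images refuse micrometre-denominated profiling", {
  px <- matrix(sample.int(256, 32 * 32, replace = TRUE) - 1L, 32, 32)
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(px / 255, path, bits.per.sample = 8)
  st <- load_image(path)
  expect_null(st$pixel_size_um)
  lc3b <- max_project(st, 1)
  puncta <- detect_puncta(lc3b, threshold = 300)
  expect_error(radial_profile(puncta, c(y = 1, x = 1)), "calibration")
})

test_that("missing files and bad axes arguments raise clear errors", {
  expect_error(load_image("/nonexistent/img.tif"), "does not exist")
  px <- matrix(0.5, 8, 8)
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(px, path)
  expect_error(load_image(path, axes = "weird"), "axes")
})

test_that("projection commutes with cropping", {
  set.seed(11)
  vox <- array(runif(2 * 3 * 20 * 20), dim = c(2, 3, 20, 20))
  st <- image_stack(round(vox * 100), c("a", "b"), pixel_size_um = 1)
  roi <- c(3, 12, 5, 18)
  a <- crop_projection(max_project(st, "b"), roi)
  cropped_vox <- st$voxels[, , roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  b <- max_project(image_stack(cropped_vox, c("a", "b"), pixel_size_um = 1), "b")
  expect_equal(unclass(a), unclass(b), ignore_attr = TRUE)
})

test_that("growth-axis normalisation makes growth point toward +y", {
  px <- matrix(0, 4, 3); px[4, 2] <- 9  # tip at large y
  img <- projection2d(px, 1, "sprout")
  expect_equal(unclass(orient_growth_axis(img, "+y")), px, ignore_attr = TRUE)
  up <- unclass(orient_growth_axis(img, "-y"))
  expect_equal(which(up == 9, arr.ind = TRUE)[1], 1)
  # growth toward +x becomes growth toward +y
  pxx <- matrix(0, 3, 5); pxx[2, 5] <- 9
  right <- orient_growth_axis(projection2d(pxx, 1), "+x")
  expect_equal(dim(right), c(5, 3))
  expect_equal(which(unclass(right) == 9, arr.ind = TRUE)[1], 5)
  pxl <- matrix(0, 3, 5); pxl[2, 1] <- 9
  left <- orient_growth_axis(projection2d(pxl, 1), "-x")
  expect_equal(which(unclass(left) == 9, arr.ind = TRUE)[1], 5)
})

test_that("multi-plane files without metadata demand an axes flag", {
  planes <- list(matrix(0.1, 8, 8), matrix(0.2, 8, 8))
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(planes, path)
  expect_error(load_image(path), "Ambiguous axis order")
  st <- load_image(path, axes = "c")
  expect_equal(dim(st$voxels)[1], 2)
  st2 <- load_image(path, axes = "z")
  expect_equal(dim(st2$voxels)[2], 2)
})
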