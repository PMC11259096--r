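test_that("blur is the identity at sigma 0 and on constant images", {
  s <- tiny_stack()
  expect_identical(blur_stack(s, 0)$voxels, s$voxels)
  const <- image_stack(array(7, c(10, 10, 2)), 1)
  expect_equal(blur_stack(const, 2)$voxels, const$voxels, tolerance = 1e-12)
  expect_error(blur_stack(s, -1), ">= 0")
})

test_that("blur conserves total intensity of interior-supported content", {
  v <- array(0, c(41, 41, 2))
  v[15:25, 15:25, ] <- 50
  s <- image_stack(v, 1)
  b <- blur_stack(s, 2)
  expect_lt(abs(sum(b$voxels) - sum(v)) / sum(v), 0.001)
})

test_that("background filters behave per method", {
  const <- image_stack(array(3, c(20, 20, 2)), 1)
  expect_equal(max(abs(background_filter(const, "tophat", 5)$voxels)), 0, tolerance = 1e-9)

  # impulse noise removed by a 3 px median, checked against a brute-force median
  set.seed(8)
  base <- matrix(10, 21, 21)
  base[cbind(sample(3:19, 6), sample(3:19, 6))] <- 200
  s <- image_stack(array(base, c(21, 21, 1)), 1)
  filt <- background_filter(s, "median", 3)$voxels[, , 1]
  brute <- base
  for (i in 2:20) {
    for (j in 2:20) {
      brute[i, j] <- median(base[(i - 1):(i + 1), (j - 1):(j + 1)])
    }
  }
  expect_equal(filt[2:20, 2:20], brute[2:20, 2:20], tolerance = 1e-6)
  expect_true(all(filt[2:20, 2:20] == 10))

  expect_error(background_filter(s, "median", 0.4), "smaller than one pixel")
})

test_that("background filtering keeps tube foreground (mask IoU >= 0.95)", {
  ph <- generate_vessel_phantom(vessel_phantom_spec("straight_tube",
    length_um = 80, noise_sd = 0, seed = 1
  ))
  with_filter <- preprocess_stack(ph$stack,
    sigma_um = 0, filter = "median",
    threshold = "otsu_global", min_object_voxels = 0
  )$voxels
  without <- preprocess_stack(ph$stack,
    sigma_um = 0, filter = NULL,
    threshold = "otsu_global", min_object_voxels = 0
  )$voxels
  iou <- sum(with_filter & without) / sum(with_filter | without)
  expect_gte(iou, 0.95)
})

test_that("binarize recovers an exhaustively-searched threshold on two-valued images", {
  v <- array(10, c(12, 12, 2))
  v[4:8, 4:8, ] <- 200
  s <- image_stack(v, 1)
  m <- binarize(s, "otsu_global")
  expect_identical(m$voxels, v == 200)
  # exhaustive-search oracle: any threshold in (10, 200) separates the classes;
  # the recorded threshold must lie in that interval
  expect_gt(m$provenance$threshold, 10)
  expect_lt(m$provenance$threshold, 200)

  # fixed threshold above the maximum -> empty mask
  expect_false(any(binarize(s, "fixed", value = 201)$voxels))
  # inverting intensities with the complement threshold complements the mask
  mc <- binarize(image_stack(300 - v, 1), "fixed", value = 300 - 110)
  mf <- binarize(s, "fixed", value = 110)
  expect_identical(mc$voxels, !mf$voxels)

  expect_error(binarize(image_stack(array(5, c(4, 4)), 1), "otsu_global"), "constant")
})

test_that("masks are monotone in a fixed threshold", {
  s <- tiny_stack(c(15, 15, 3), seed = 21)
  lo <- binarize(s, "fixed", value = 30)$voxels
  hi <- binarize(s, "fixed", value = 60)$voxels
  expect_true(all(hi <= lo)) # higher threshold -> subset
})

test_that("clean_mask removes small components and can fill holes", {
  v <- array(FALSE, c(10, 10, 3))
  v[2:5, 2:5, 1:2] <- TRUE # 32-voxel block
  v[9, 9, 3] <- TRUE # isolated voxel
  m <- image_stack(v, 1)
  expect_identical(clean_mask(m, 0)$voxels, v)
  cleaned <- clean_mask(m, 2)$voxels
  expect_false(cleaned[9, 9, 3])
  expect_equal(sum(cleaned), 32)

  ring <- array(FALSE, c(9, 9, 1))
  ring[3:7, 3:7, 1] <- TRUE
  ring[5, 5, 1] <- FALSE
  filled <- clean_mask(image_stack(ring, 1), 0, fill_holes = TRUE)$voxels
  expect_true(filled[5, 5, 1])
})

test_that("full preprocess recovers a noise-free tube mask with IoU >= 0.95", {
  # a well-resolved tube: at radii near the voxel scale the median filter
  # shaves staircase edge voxels and the IoU floor is not attainable
  ph <- generate_vessel_phantom(vessel_phantom_spec("straight_tube",
    tube_radius_um = 5, noise_sd = 0, psf_sigma_um = 0.5, seed = 1
  ))
  mask <- preprocess_stack(ph$stack, sigma_um = 1, threshold = "otsu_global")
  iou <- sum(mask$voxels & ph$mask$voxels) / sum(mask$voxels | ph$mask$voxels)
  expect_gte(iou, 0.95)
})

test_that("provenance records every applied parameter", {
  s <- tiny_stack(c(12, 12, 2))
  m <- preprocess_stack(s, sigma_um = 1.5, filter = "median", threshold = "otsu_per_slice")
  p <- m$provenance
  expect_equal(p$blur_sigma_um, 1.5)
  expect_equal(p$filter, "median")
  expect_equal(p$threshold_method, "otsu_per_slice")
  expect_length(p$threshold, 2)
  expect_equal(p$min_object_voxels, 27)
})
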