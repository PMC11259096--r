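test_that("phantom generators are pure functions of their spec", {
  sp <- vessel_phantom_spec("random_tree", n_segments = 6, grid_dim = c(60, 60, 60), seed = 42)
  a <- generate_vessel_phantom(sp)
  b <- generate_vessel_phantom(sp)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth, b$truth)
  # the caller's RNG stream is untouched
  set.seed(5)
  before <- rnorm(1)
  set.seed(5)
  invisible(generate_vessel_phantom(sp))
  expect_identical(rnorm(1), before)
})

test_that("straight tube and Y junction ground truth is forced by construction", {
  tube <- generate_vessel_phantom(vessel_phantom_spec("straight_tube", length_um = 200, seed = 1))
  expect_equal(tube$truth$n_segments, 1)
  expect_equal(tube$truth$n_endpoints, 2)
  expect_equal(tube$truth$n_junctions, 0)
  expect_equal(tube$truth$total_length_um, 200)

  y <- generate_vessel_phantom(vessel_phantom_spec("y_junction", seed = 1))
  expect_equal(y$truth$n_segments, 3)
  expect_equal(y$truth$n_junctions, 1)
  expect_equal(y$truth$n_endpoints, 3)
  expect_equal(y$truth$total_length_um, sum(y$truth$segment_lengths_um))
})

test_that("random trees satisfy the tree identity and reach their target", {
  for (s in 1:5) {
    tr <- generate_vessel_phantom(vessel_phantom_spec("random_tree", n_segments = 10, seed = s))
    tt <- tr$truth
    expect_equal(tt$n_endpoints + tt$n_junctions, tt$n_segments + 1)
    expect_gte(tt$n_segments, 10)
    expect_equal(tt$total_length_um, sum(tt$segment_lengths_um))
  }
})

test_that("geometry that does not fit the grid errors", {
  expect_error(
    generate_vessel_phantom(vessel_phantom_spec("straight_tube",
      length_um = 500, grid_dim = c(20, 100, 20), voxel_size_um = 1
    )),
    "fit"
  )
  expect_error(vessel_phantom_spec("straight_tube", tube_radius_um = 0.4), "voxel")
})

test_that("coloc phantom realizes the requested overlap exactly", {
  ph <- generate_coloc_phantom(c(40, 50, 10), n_a = 10000, fraction = 0.3)
  expect_identical(sum(ph$mask_a & ph$mask_b), 3000L)
  expect_equal(ph$realized_fraction, 0.3)

  full <- generate_coloc_phantom(c(10, 10, 10), n_a = 400, fraction = 1)
  expect_true(all(full$mask_a <= full$mask_b)) # B contains A
  expect_equal(full$realized_fraction, 1)

  none <- generate_coloc_phantom(c(10, 10, 10), n_a = 400, fraction = 0)
  expect_false(any(none$mask_a & none$mask_b))
  expect_equal(none$realized_fraction, 0)

  expect_error(generate_coloc_phantom(c(5, 5, 5), n_a = 0, fraction = 0.5), "non-empty")
  # rounding bound: |realized - f| <= 1/|A|
  odd <- generate_coloc_phantom(c(20, 20, 20), n_a = 333, fraction = 0.5)
  expect_lte(abs(odd$realized_fraction - 0.5), 1 / 333)
})

test_that("spheroid phantom true areas follow the closed form", {
  # disk-only: pi r^2, unit-converted
  sp <- spheroid_phantom_spec(
    days = 0, core_radius_um = 200, n_protrusions = 0,
    noise_sd = 0, blur_sigma_px = 0, seed = 2
  )
  out <- generate_spheroid_series(sp)
  expect_equal(out$truth$true_area_mm2, pi * 200^2 / 1e6)
  # pixel-count rasterization oracle within 1%
  raster_area <- sum(out$images[[1]]$voxels > 100) * pixel_area_mm2(sp$pixel_size_um)
  expect_lt(abs(raster_area - out$truth$true_area_mm2) / out$truth$true_area_mm2, 0.01)

  # zero growth over days -> identical true areas
  flat <- generate_spheroid_series(spheroid_phantom_spec(
    days = 0:2, core_radius_um = 150, protrusion_growth_um = 0, seed = 3
  ))
  expect_equal(length(unique(flat$truth$true_area_mm2)), 1L)

  # protrusions add n * w * len exactly
  gr <- spheroid_phantom_spec(
    days = 0:2, core_radius_um = 150, n_protrusions = 6,
    protrusion_width_um = 20, protrusion_growth_um = 30, seed = 4
  )
  tr <- generate_spheroid_series(gr)$truth
  expect_equal(tr$true_area_mm2[3], (pi * 150^2 + 6 * 20 * 60) / 1e6)

  expect_error(spheroid_phantom_spec(days = 1:3), "start at 0")
  expect_error(spheroid_phantom_spec(core_radius_um = -5), "positive")
})

test_that("array membrane truth is normalized and reference spots behave", {
  # all targets at negative-control level -> normalized truth 0
  lay <- demo_array_layout()
  targets <- unique(lay$spots$target[lay$spots$role == "target"])
  zero <- array_phantom_spec(lay, setNames(rep(0, length(targets)), targets), seed = 5)
  expect_true(all(generate_array_membrane(zero)$truth$true_level == 0))
  # one target at positive-control level -> 1
  lv <- setNames(rep(0.4, length(targets)), targets)
  lv[3] <- 1
  one <- generate_array_membrane(array_phantom_spec(lay, lv, seed = 5))
  expect_equal(one$truth$true_level[3], 1)
  # global affine distortion leaves the truth table unchanged
  base <- generate_array_membrane(array_phantom_spec(lay, lv, seed = 5))
  warped <- generate_array_membrane(array_phantom_spec(lay, lv, gain = 2, offset = 10, seed = 5))
  expect_identical(base$truth, warped$truth)
  expect_false(identical(base$image$voxels, warped$image$voxels))
})

test_that("stromal density follows the endothelial density and ratio", {
  expect_equal(stromal_density(500000, 2, 1), 250000)
  expect_equal(stromal_density(500000, 1, 1), 500000)
  expect_equal(stromal_density(500000, 1, 2), 1000000)
  expect_error(stromal_density(500000, 0, 1), "positive")
  expect_error(stromal_density(-1, 1, 1), "positive")
})
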