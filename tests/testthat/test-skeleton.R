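test_that("empty masks give empty skeletons and empty graphs", {
  m <- image_stack(array(FALSE, c(6, 6, 3)), 1)
  sk <- skeletonize(m)
  expect_false(any(sk$voxels))
  g <- build_skeleton_graph(sk)
  expect_equal(nrow(g$segments), 0)
  metrics <- measure_network(g, 1e-3)
  expect_equal(metrics$n_vessels, 0)
  expect_equal(metrics$total_length_per_mm3, 0)
  expect_true(is.na(metrics$avg_branch_length_um))
})

test_that("a straight voxel path measures its hand-counted step sum", {
  g <- build_skeleton_graph(line_mask(11, voxel = 1), prune_um = 0)
  expect_equal(nrow(g$segments), 1)
  expect_equal(g$segments$length_um, 10) # 11 voxels, 10 unit steps
  expect_equal(sum(g$nodes$kind == "endpoint"), 2)
  expect_equal(sum(g$nodes$kind == "junction"), 0)
})

test_that("a thick straight tube thins to one path with two endpoints", {
  ph <- generate_vessel_phantom(vessel_phantom_spec("straight_tube",
    length_um = 80, tube_radius_um = 3, noise_sd = 0, psf_sigma_um = 0, seed = 1
  ))
  sk <- skeletonize(ph$mask)
  g <- build_skeleton_graph(sk)
  expect_equal(nrow(g$segments), 1)
  expect_equal(sum(g$nodes$kind == "endpoint"), 2)
  # one voxel wide: no 2x2x2 block anywhere triggers the thickness warning
  expect_silent(build_skeleton_graph(sk))
})

test_that("skeletonization preserves the number of connected components", {
  set.seed(31)
  v <- array(FALSE, c(30, 30, 8))
  v[3:8, 3:20, 3:6] <- TRUE
  v[15:20, 10:28, 3:6] <- TRUE
  v[25:28, 2:6, 2:4] <- TRUE
  m <- image_stack(v, 1)
  expect_equal(max(label_components(skeletonize(m)$voxels)), max(label_components(v)))
})

test_that("a closed ring becomes one cyclic segment with no endpoints", {
  # annulus in one slice; thinning preserves the hole, giving a closed curve
  v <- array(FALSE, c(25, 25, 3))
  for (y in 1:25) {
    for (x in 1:25) {
      r <- sqrt((y - 13)^2 + (x - 13)^2)
      v[y, x, 2] <- r >= 4 && r <= 9
    }
  }
  # default spur pruning removes the short thinning artefacts at the rim
  g <- build_skeleton_graph(skeletonize(image_stack(v, 1)))
  expect_equal(nrow(g$segments), 1)
  expect_true(g$segments$cyclic)
  expect_equal(sum(g$nodes$kind == "endpoint"), 0)
  expect_equal(sum(g$nodes$kind == "junction"), 0)
})

test_that("dilating a tube mask leaves endpoint and junction counts unchanged", {
  ph <- generate_vessel_phantom(vessel_phantom_spec("straight_tube",
    length_um = 80, noise_sd = 0, psf_sigma_um = 0, seed = 2
  ))
  g1 <- build_skeleton_graph(skeletonize(ph$mask))
  v <- ph$mask$voxels
  d <- dim(v)
  grown <- v
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    shifted <- array(FALSE, d)
    src_y <- pmax(1, 1 - off[1]):pmin(d[1], d[1] - off[1])
    shifted[src_y + off[1], , ] <- v[src_y, , ] # y only; x/z below
    if (off[2] != 0) {
      shifted <- array(FALSE, d)
      src <- pmax(1, 1 - off[2]):pmin(d[2], d[2] - off[2])
      shifted[, src + off[2], ] <- v[, src, ]
    }
    if (off[3] != 0) {
      shifted <- array(FALSE, d)
      src <- pmax(1, 1 - off[3]):pmin(d[3], d[3] - off[3])
      shifted[, , src + off[3]] <- v[, , src]
    }
    grown <- grown | shifted
  }
  g2 <- build_skeleton_graph(skeletonize(image_stack(grown, ph$mask$voxel_size_um)))
  expect_equal(sum(g2$nodes$kind == "endpoint"), sum(g1$nodes$kind == "endpoint"))
  expect_equal(sum(g2$nodes$kind == "junction"), sum(g1$nodes$kind == "junction"))
})

test_that("handshake identity holds: node degrees sum to twice the segment count", {
  for (s in 1:3) {
    ph <- generate_vessel_phantom(vessel_phantom_spec("random_tree",
      n_segments = 8, seed = s
    ))
    g <- build_skeleton_graph(skeletonize(ph$mask))
    acyclic <- g$segments[!g$segments$cyclic, ]
    expect_equal(sum(g$nodes$degree), 2 * nrow(acyclic))
    # acyclic phantom: endpoints + junctions = segments + 1 per component
    expect_equal(
      sum(g$nodes$kind == "endpoint") + sum(g$nodes$kind == "junction"),
      nrow(g$segments) + g$n_components
    )
  }
})

test_that("lengths scale linearly and density inversely quadratically with voxel size", {
  ph <- generate_vessel_phantom(vessel_phantom_spec("y_junction",
    noise_sd = 0, psf_sigma_um = 0, seed = 3
  ))
  c_scale <- 2.5
  m1 <- measure_mask(ph$mask)
  scaled <- image_stack(ph$mask$voxels, ph$mask$voxel_size_um * c_scale)
  m2 <- measure_mask(scaled, prune_um = 3 * c_scale)
  expect_equal(m2$total_length_um, c_scale * m1$total_length_um)
  expect_equal(m2$total_length_per_mm3, m1$total_length_per_mm3 / c_scale^2)
  expect_equal(m2$n_vessels, m1$n_vessels)
})

test_that("network metrics arithmetic matches the definitions", {
  # three 50 um segments through one junction in a known volume
  seg <- tibble::tibble(
    segment = 1:3, node_from = c(2L, 2L, 2L), node_to = c(1L, 3L, 4L),
    length_um = c(50, 50, 50), n_voxels = c(26L, 26L, 26L),
    component = 1L, cyclic = FALSE
  )
  nodes <- tibble::tibble(
    node = 1:4, kind = c("endpoint", "junction", "endpoint", "endpoint"),
    degree = c(1, 3, 1, 1), y_um = 0, x_um = 0, z_um = 0, component = 1L
  )
  g <- structure(
    list(
      nodes = nodes, segments = seg, paths = list(), n_components = 1L,
      voxel_size_um = c(1, 1, 1), prune_um = 0, pruned_segments = 0L
    ),
    class = "skeleton_graph"
  )
  m <- measure_network(g, 0.001)
  expect_equal(m$total_length_um, 150)
  expect_equal(m$total_length_per_mm3, 150000)
  expect_equal(m$avg_branch_length_um, 50)
  expect_equal(m$n_vessels, 3)
  expect_equal(m$n_branches, 4) # 1 branch point + 3 endpoints
  expect_error(measure_network(g, 0), "positive")
})

test_that("ROI averaging is an unweighted mean and order-invariant", {
  m1 <- measure_network(build_skeleton_graph(line_mask(11)), 1e-3)
  expect_equal(average_rois(m1), m1)
  two <- dplyr::bind_rows(
    dplyr::mutate(m1, total_length_per_mm3 = 100),
    dplyr::mutate(m1, total_length_per_mm3 = 200)
  )
  expect_equal(average_rois(two)$total_length_per_mm3, 150)
  expect_equal(average_rois(two), average_rois(two[2:1, ]))
  expect_error(average_rois(m1[0, ]), "at least one")
})
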