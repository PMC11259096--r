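#' @section Phantom generators:
#' Every generator in this file is a pure function of its spec: the RNG
#' seed is part of the spec, the caller's RNG state is saved and restored,
#' and identical specs give byte-identical outputs.
#' @noRd
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Separable Gaussian blur along one array axis; sigma in pixels.
# Truncated-kernel rows are renormalized, which is the reflective-mass
# convention: total intensity of interior-supported content is conserved.
blur_axis <- function(a, axis, sigma_px) {
  if (sigma_px <= 0) return(a)
  n <- dim(a)[axis]
  half <- max(1L, ceiling(3 * sigma_px))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) {
    d <- abs(i - j)
    ifelse(d <= half, exp(-(d^2) / (2 * sigma_px^2)), 0)
  })
  K <- K / rowSums(K)
  d <- dim(a)
  perm <- c(axis, setdiff(seq_along(d), axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  m <- K %*% m
  ap <- array(m, dim(ap))
  aperm(ap, order(perm))
}

gauss_blur_um <- function(a, sigma_um, voxel_size_um) {
  for (ax in seq_along(dim(a))) {
    a <- blur_axis(a, ax, sigma_um / voxel_size_um[ax])
  }
  a
}

#' Specification for a tubular vessel phantom
#'
#' Describes a synthetic vessel network rasterized into a calibrated
#' z-stack: tube centrelines with a known topology, a tube radius, and a
#' confocal-like intensity model (foreground/background means, Gaussian
#' PSF blur applied before additive Gaussian noise). Tube and Y-junction
#' phantoms default to an isotropic 1 um grid sized to the geometry;
#' `random_tree` defaults to an isotropic 2 um grid large enough to hold
#' a branching tree. An anisotropic 5 um z-step, as in typical confocal
#' hydrogel stacks, is supported via `voxel_size_um` provided the tube
#' radius spans at least one voxel on every axis.
#'
#' @param topology `"straight_tube"`, `"y_junction"` or `"random_tree"`.
#' @param grid_dim integer voxel counts `(y, x, z)`; `NULL` picks a
#'   topology-appropriate default.
#' @param voxel_size_um per-axis voxel size `(y, x, z)` in micrometres.
#' @param tube_radius_um tube radius in micrometres; must span at least
#'   one voxel on every axis. Defaults to 3 (straight tube, Y junction)
#'   and 4 for `random_tree` — two voxels on its default 2 um grid, since
#'   tubes much thinner than two voxels are below the resolution at which
#'   thinning and filtering behave reliably.
#' @param length_um centreline length for `straight_tube`.
#' @param stem_um,branch_um,branch_angle_deg geometry for `y_junction`.
#' @param n_segments target segment count for `random_tree`.
#' @param branch_prob probability a grown tip bifurcates (random_tree).
#' @param seg_len_um length-2 range of segment lengths (random_tree).
#' @param angle_jitter_deg jitter of the bifurcation half-angle.
#' @param fg,bg,noise_sd,psf_sigma_um intensity model: foreground and
#'   background means, additive Gaussian noise SD, and PSF blur sigma in
#'   micrometres (isotropic in physical units, applied before noise).
#' @param seed integer RNG seed; part of the spec, so the phantom is a
#'   deterministic function of this object.
#' @return A `vessel_phantom_spec` list.
#' @export
vessel_phantom_spec <- function(topology = c("straight_tube", "y_junction", "random_tree"),
                                grid_dim = NULL,
                                voxel_size_um = NULL,
                                tube_radius_um = if (match.arg(topology) == "random_tree") 4 else 3,
                                length_um = 200,
                                stem_um = 80, branch_um = 70, branch_angle_deg = 35,
                                n_segments = 12, branch_prob = 1,
                                seg_len_um = c(28, 45), angle_jitter_deg = 10,
                                fg = 200, bg = 20, noise_sd = 10, psf_sigma_um = 1,
                                seed = 1L) {
  topology <- match.arg(topology)
  if (is.null(voxel_size_um)) {
    voxel_size_um <- if (topology == "random_tree") c(2, 2, 2) else c(1, 1, 1)
  }
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3)
  if (is.null(grid_dim)) {
    grid_dim <- switch(topology,
      straight_tube = c(
        ceiling(6 * tube_radius_um / voxel_size_um[1]) + 9L,
        ceiling((length_um + 6 * tube_radius_um) / voxel_size_um[2]) + 9L,
        ceiling(6 * tube_radius_um / voxel_size_um[3]) + 5L
      ),
      y_junction = c(
        ceiling((2.2 * branch_um + 8 * tube_radius_um) / voxel_size_um[1]) + 9L,
        ceiling((stem_um + branch_um + 8 * tube_radius_um) / voxel_size_um[2]) + 9L,
        ceiling(6 * tube_radius_um / voxel_size_um[3]) + 5L
      ),
      random_tree = ceiling(210 / voxel_size_um) + 1L
    )
  }
  grid_dim <- as.integer(grid_dim)
  if (tube_radius_um < max(voxel_size_um)) {
    abort("`tube_radius_um` must span at least one voxel on every axis.")
  }
  if (noise_sd < 0 || psf_sigma_um < 0) abort("Noise SD and PSF sigma must be >= 0.")
  structure(
    list(
      topology = topology, grid_dim = grid_dim, voxel_size_um = voxel_size_um,
      tube_radius_um = tube_radius_um, length_um = length_um,
      stem_um = stem_um, branch_um = branch_um, branch_angle_deg = branch_angle_deg,
      n_segments = n_segments, branch_prob = branch_prob,
      seg_len_um = seg_len_um, angle_jitter_deg = angle_jitter_deg,
      fg = fg, bg = bg, noise_sd = noise_sd, psf_sigma_um = psf_sigma_um,
      seed = as.integer(seed)
    ),
    class = "vessel_phantom_spec"
  )
}

polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# Rasterize tubes of radius r (um) around polylines (physical um coords,
# columns y,x,z) into a logical array. Distance computed in physical units
# per segment within a bounding box, so anisotropic voxels are handled.
rasterize_tubes <- function(polylines, radius_um, grid_dim, voxel_size_um) {
  mask <- array(FALSE, grid_dim)
  vs <- voxel_size_um
  for (p in polylines) {
    for (k in seq_len(nrow(p) - 1)) {
      p0 <- p[k, ]
      p1 <- p[k + 1, ]
      lo <- pmin(p0, p1) - radius_um
      hi <- pmax(p0, p1) + radius_um
      i0 <- pmax(1L, floor(lo / vs) )
      i1 <- pmin(grid_dim, ceiling(hi / vs) + 2L)
      if (any(i0 > i1)) next
      ys <- (seq.int(i0[1], i1[1]) - 1) * vs[1]
      xs <- (seq.int(i0[2], i1[2]) - 1) * vs[2]
      zs <- (seq.int(i0[3], i1[3]) - 1) * vs[3]
      g <- expand.grid(y = ys, x = xs, z = zs, KEEP.OUT.ATTRS = FALSE)
      v <- p1 - p0
      vv <- sum(v^2)
      w <- cbind(g$y - p0[1], g$x - p0[2], g$z - p0[3])
      t <- if (vv > 0) pmin(1, pmax(0, (w %*% v) / vv)) else rep(0, nrow(w))
      d2 <- (w[, 1] - t * v[1])^2 + (w[, 2] - t * v[2])^2 + (w[, 3] - t * v[3])^2
      inside <- array(d2 <= radius_um^2, c(length(ys), length(xs), length(zs)))
      sub <- mask[seq.int(i0[1], i1[1]), seq.int(i0[2], i1[2]), seq.int(i0[3], i1[3])]
      mask[seq.int(i0[1], i1[1]), seq.int(i0[2], i1[2]), seq.int(i0[3], i1[3])] <-
        sub | inside
    }
  }
  mask
}

unit <- function(v) v / sqrt(sum(v^2))

perp_unit <- function(v) {
  # a random-ish unit vector perpendicular to v (deterministic given RNG state)
  a <- unit(stats::rnorm(3))
  w <- a - sum(a * v) * v
  while (sqrt(sum(w^2)) < 1e-6) {
    a <- unit(stats::rnorm(3))
    w <- a - sum(a * v) * v
  }
  unit(w)
}

rotate_towards <- function(dir, axis, angle_rad) {
  unit(cos(angle_rad) * dir + sin(angle_rad) * axis)
}

grow_random_tree <- function(spec) {
  vs <- spec$voxel_size_um
  extent <- (spec$grid_dim - 1) * vs
  margin <- spec$tube_radius_um + 2 * max(vs)
  r <- spec$tube_radius_um
  clearance <- 2 * r + max(vs) # inter-segment clearance so topology survives
  joint_excl <- 2.2 * r

  sample_pts <- function(p0, p1) {
    L <- sqrt(sum((p1 - p0)^2))
    n <- max(2L, ceiling(L / 1.5))
    t <- seq(0, 1, length.out = n)
    cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]),
          p0[3] + t * (p1[3] - p0[3]))
  }

  segs <- list() # each: list(p0, p1, parent, children = integer())
  pts <- matrix(numeric(0), ncol = 3)
  pts_seg <- integer(0)

  ok_segment <- function(p0, p1, parent_id) {
    if (any(p1 < margin) || any(p1 > extent - margin)) return(FALSE)
    cand <- sample_pts(p0, p1)
    far <- sqrt(rowSums((cand - matrix(p0, nrow(cand), 3, byrow = TRUE))^2)) > joint_excl
    if (!any(far) || nrow(pts) == 0) return(TRUE)
    keep <- rep(TRUE, nrow(pts))
    if (!is.null(parent_id)) keep <- keep & pts_seg != parent_id
    # points of other segments near the shared joint are allowed
    near_joint <- sqrt(rowSums((pts - matrix(p0, nrow(pts), 3, byrow = TRUE))^2)) <= joint_excl
    keep <- keep & !near_joint
    if (!any(keep)) return(TRUE)
    other <- pts[keep, , drop = FALSE]
    cf <- cand[far, , drop = FALSE]
    for (i in seq_len(nrow(cf))) {
      d2 <- (other[, 1] - cf[i, 1])^2 + (other[, 2] - cf[i, 2])^2 +
        (other[, 3] - cf[i, 3])^2
      if (min(d2) < clearance^2) return(FALSE)
    }
    TRUE
  }

  add_segment <- function(p0, dir, parent_id) {
    for (try in 1:10) {
      L <- stats::runif(1, spec$seg_len_um[1], spec$seg_len_um[2])
      p1 <- p0 + L * dir
      if (ok_segment(p0, p1, parent_id)) {
        id <- length(segs) + 1L
        segs[[id]] <<- list(p0 = p0, p1 = p1, parent = parent_id,
                            children = integer(0))
        if (!is.null(parent_id)) {
          segs[[parent_id]]$children <<- c(segs[[parent_id]]$children, id)
        }
        sp <- sample_pts(p0, p1)
        pts <<- rbind(pts, sp)
        pts_seg <<- c(pts_seg, rep(id, nrow(sp)))
        return(id)
      }
      # jitter the direction and retry
      ax <- perp_unit(dir)
      dir <- rotate_towards(dir, ax, stats::runif(1, -0.5, 0.5))
    }
    NULL
  }

  root_p <- c(extent[1] / 2, margin, extent[3] / 2)
  root_dir <- c(0, 1, 0)
  root <- add_segment(root_p, root_dir, NULL)
  if (is.null(root)) abort("Random tree does not fit the grid.")
  tips <- list(list(id = root, dir = root_dir))
  while (length(tips) > 0 && length(segs) < spec$n_segments) {
    tip <- tips[[1]]
    tips <- tips[-1]
    if (stats::runif(1) > spec$branch_prob) next
    seg <- segs[[tip$id]]
    # retry the whole bifurcation a few times so both children usually fit;
    # single-child joints are merged below and waste a growth slot
    for (attempt in 1:5) {
      half <- (25 + stats::runif(1, -spec$angle_jitter_deg, spec$angle_jitter_deg)) * pi / 180
      ax <- perp_unit(tip$dir)
      grown <- list()
      for (sgn in c(-1, 1)) {
        d <- rotate_towards(tip$dir, ax, sgn * half)
        id <- add_segment(seg$p1, d, tip$id)
        if (!is.null(id)) grown <- c(grown, list(list(id = id, dir = d)))
      }
      if (length(grown) == 2 || attempt == 5) {
        tips <- c(tips, grown)
        break
      }
      # roll back the lone child and try a different plane
      for (gch in grown) {
        rid <- gch$id
        segs[[tip$id]]$children <- setdiff(segs[[tip$id]]$children, rid)
        keep <- pts_seg != rid
        pts <- pts[keep, , drop = FALSE]
        pts_seg <- pts_seg[keep]
        segs[rid] <- list(NULL)
      }
      segs <- segs[!vapply(segs, is.null, logical(1))]
    }
  }

  # Merge chains through degree-2 joints (a bifurcation where only one
  # child could grow) so ground-truth segments match graph segments.
  absorbed <- rep(FALSE, length(segs))
  repeat {
    merged <- FALSE
    for (i in seq_along(segs)) {
      if (absorbed[i]) next
      ch <- segs[[i]]$children
      ch <- ch[!absorbed[ch]]
      if (length(ch) == 1L) {
        j <- ch
        segs[[i]]$p1 <- segs[[j]]$p1
        segs[[i]]$mid <- rbind(segs[[i]]$mid, segs[[j]]$p0, segs[[j]]$mid)
        segs[[i]]$children <- segs[[j]]$children
        for (k in segs[[j]]$children) segs[[k]]$parent <- i
        absorbed[j] <- TRUE
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  segs[!absorbed]
}

#' Generate a tubular vessel phantom with exact ground truth
#'
#' Rasterizes the spec's centrelines as tubes (voxel centres within the
#' tube radius in physical units), applies the Gaussian PSF and additive
#' noise, and returns both the intensity stack and a ground-truth record:
#' centreline polylines, per-segment lengths, and exact segment /
#' junction / endpoint counts. For acyclic topologies the ground truth
#' satisfies `n_endpoints + n_junctions == n_segments + 1`.
#'
#' @param spec a [vessel_phantom_spec()].
#' @return A list with elements `stack` (an [image_stack()]), `mask`
#'   (the noise-free rasterized tube mask, an [image_stack()] of
#'   logicals) and `truth` (list: `polylines`, `segment_lengths_um`,
#'   `total_length_um`, `n_segments`, `n_junctions`, `n_endpoints`).
#' @examples
#' ph <- generate_vessel_phantom(vessel_phantom_spec("y_junction", seed = 7))
#' ph$truth$n_segments # 3
#' @export
generate_vessel_phantom <- function(spec) {
  if (!inherits(spec, "vessel_phantom_spec")) {
    abort("`spec` must be a `vessel_phantom_spec`.")
  }
  vs <- spec$voxel_size_um
  extent <- (spec$grid_dim - 1) * vs
  r <- spec$tube_radius_um
  margin <- r + 2 * max(vs)
  with_seed(spec$seed, {
    if (spec$topology == "straight_tube") {
      if (spec$length_um + 2 * margin > extent[2]) {
        abort("Tube length does not fit the grid.")
      }
      x0 <- (extent[2] - spec$length_um) / 2
      c0 <- c(extent[1] / 2, x0, extent[3] / 2)
      c1 <- c(extent[1] / 2, x0 + spec$length_um, extent[3] / 2)
      polylines <- list(rbind(c0, c1))
      n_junc <- 0L
      n_end <- 2L
    } else if (spec$topology == "y_junction") {
      th <- spec$branch_angle_deg * pi / 180
      if (spec$stem_um + spec$branch_um * cos(th) + 2 * margin > extent[2] ||
          2 * spec$branch_um * sin(th) + 2 * margin > extent[1]) {
        abort("Y junction does not fit the grid.")
      }
      base <- c(extent[1] / 2, margin, extent[3] / 2)
      joint <- base + c(0, spec$stem_um, 0)
      b1 <- joint + spec$branch_um * c(sin(th), cos(th), 0)
      b2 <- joint + spec$branch_um * c(-sin(th), cos(th), 0)
      polylines <- list(rbind(base, joint), rbind(joint, b1), rbind(joint, b2))
      n_junc <- 1L
      n_end <- 3L
    } else {
      segs <- grow_random_tree(spec)
      polylines <- lapply(segs, function(s) {
        rbind(s$p0, s$mid, s$p1)
      })
      n_children <- vapply(segs, function(s) length(s$children), integer(1))
      n_junc <- sum(n_children == 2L)
      n_end <- sum(n_children == 0L) + 1L # leaves plus the root
    }
    # Snap vertices to voxel centres so axis-aligned tubes have odd-width
    # cross-sections (an axis midway between voxel rows rasterizes to an
    # even-width slab, which curve thinning handles poorly). Ground truth
    # is computed from the snapped polylines, so it stays exact.
    polylines <- lapply(polylines, function(p) {
      snapped <- round(sweep(p, 2, vs, `/`))
      sweep(snapped, 2, vs, `*`)
    })
    seg_len <- vapply(polylines, polyline_length, numeric(1))
    truth <- list(
      polylines = polylines,
      segment_lengths_um = seg_len,
      total_length_um = sum(seg_len),
      n_segments = length(polylines),
      n_junctions = n_junc,
      n_endpoints = n_end
    )
    mask <- rasterize_tubes(polylines, r, spec$grid_dim, vs)
    img <- ifelse(mask, spec$fg, spec$bg)
    img <- gauss_blur_um(img, spec$psf_sigma_um, vs)
    if (spec$noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
    }
    list(
      stack = image_stack(img, vs, channel = "phantom"),
      mask = image_stack(mask, vs, channel = "phantom_truth"),
      truth = truth
    )
  })
}

#' Construct a two-mask colocalization phantom with a known overlap
#'
#' Builds two binary masks on the same grid such that the realized
#' overlap fraction `|A & B| / |A|` equals the requested fraction up to
#' integer rounding of voxel counts (the realized exact fraction is
#' returned). Construction is deterministic: contiguous runs of voxels
#' in array order.
#'
#' @param grid_dim integer voxel counts `(y, x, z)`.
#' @param n_a number of voxels in mask A (> 0).
#' @param fraction target overlap fraction in `[0, 1]`.
#' @param n_b number of voxels in mask B; default `n_a`.
#' @return List with logical arrays `mask_a`, `mask_b` and
#'   `realized_fraction`.
#' @examples
#' ph <- generate_coloc_phantom(c(40, 50, 10), n_a = 10000, fraction = 0.3)
#' ph$realized_fraction # exactly 0.3
#' @export
generate_coloc_phantom <- function(grid_dim, n_a, fraction, n_b = n_a) {
  grid_dim <- as.integer(grid_dim)
  n_tot <- prod(grid_dim)
  if (n_a <= 0) abort("Mask A must be non-empty.")
  if (fraction < 0 || fraction > 1) abort("`fraction` must be in [0, 1].")
  k <- round(fraction * n_a)
  if (n_b < k) abort("`n_b` must be at least `fraction * n_a`.")
  if (n_a + n_b - k > n_tot) abort("Masks do not fit the grid.")
  a <- logical(n_tot)
  b <- logical(n_tot)
  a[seq_len(n_a)] <- TRUE
  if (k > 0) b[seq.int(n_a - k + 1, n_a)] <- TRUE
  if (n_b - k > 0) b[seq.int(n_a + 1, n_a + n_b - k)] <- TRUE
  dim(a) <- grid_dim
  dim(b) <- grid_dim
  list(mask_a = a, mask_b = b, realized_fraction = k / n_a)
}

#' Specification for a spheroid outgrowth phantom series
#'
#' A bright spheroid body (disk of radius `core_radius_um[day]`) with
#' `n_protrusions` rectangular protrusions radiating from the body,
#' growing by `protrusion_growth_um` per day. The true outgrowth area has
#' the closed form `pi * r^2 + n * width * length` because the rectangles
#' start on the disk boundary and extend strictly outward.
#'
#' @param days integer vector of observation days, ascending, starting 0.
#' @param pixel_size_um pixel edge length in micrometres.
#' @param core_radius_um disk radius per day (recycled if scalar).
#' @param n_protrusions,protrusion_width_um,protrusion_growth_um
#'   protrusion model; length on day `d` is `protrusion_growth_um * d`.
#' @param fg,bg,noise_sd,blur_sigma_px image model.
#' @param seed integer RNG seed.
#' @return A `spheroid_phantom_spec` list.
#' @export
spheroid_phantom_spec <- function(days = 0:3, pixel_size_um = 2,
                                  core_radius_um = 150 + 15 * days,
                                  n_protrusions = 8, protrusion_width_um = 20,
                                  protrusion_growth_um = 40,
                                  fg = 200, bg = 30, noise_sd = 8,
                                  blur_sigma_px = 1, seed = 1L) {
  if (length(days) < 1 || is.unsorted(days) || days[1] != 0) {
    abort("`days` must be ascending and start at 0.")
  }
  core_radius_um <- rep_len(core_radius_um, length(days))
  if (any(core_radius_um <= 0)) abort("Core radii must be positive.")
  structure(
    list(
      days = as.integer(days), pixel_size_um = pixel_size_um,
      core_radius_um = core_radius_um, n_protrusions = n_protrusions,
      protrusion_width_um = protrusion_width_um,
      protrusion_growth_um = protrusion_growth_um,
      fg = fg, bg = bg, noise_sd = noise_sd, blur_sigma_px = blur_sigma_px,
      seed = as.integer(seed)
    ),
    class = "spheroid_phantom_spec"
  )
}

#' Generate a spheroid outgrowth image series with closed-form true areas
#'
#' @param spec a [spheroid_phantom_spec()].
#' @return List with `images` (one [image_stack()] per day) and `truth`,
#'   a tibble with columns `day`, `true_area_mm2`.
#' @export
generate_spheroid_series <- function(spec) {
  if (!inherits(spec, "spheroid_phantom_spec")) {
    abort("`spec` must be a `spheroid_phantom_spec`.")
  }
  px <- spec$pixel_size_um
  max_r <- max(spec$core_radius_um +
    spec$protrusion_growth_um * max(spec$days))
  half <- ceiling((max_r + 8 * px) / px)
  n <- 2L * half + 1L
  ctr <- (half) * px # 0-based centre
  with_seed(spec$seed, {
    angles <- 2 * pi * seq_len(spec$n_protrusions) / spec$n_protrusions +
      stats::runif(spec$n_protrusions, -0.1, 0.1)
    images <- list()
    truth <- tibble(
      day = spec$days,
      true_area_mm2 = NA_real_
    )
    coords <- (seq_len(n) - 1) * px - ctr
    yy <- matrix(coords, n, n)
    xx <- t(yy)
    for (i in seq_along(spec$days)) {
      d <- spec$days[i]
      r <- spec$core_radius_um[i]
      len <- spec$protrusion_growth_um * d
      w <- spec$protrusion_width_um
      inside <- yy^2 + xx^2 <= r^2
      if (len > 0) {
        for (th in angles) {
          u <- c(cos(th), sin(th))
          s <- yy * u[1] + xx * u[2] - r
          t <- -yy * u[2] + xx * u[1]
          inside <- inside | (s >= 0 & s <= len & abs(t) <= w / 2)
        }
      }
      truth$true_area_mm2[i] <-
        (pi * r^2 + ifelse(len > 0, spec$n_protrusions * w * len, 0)) / 1e6
      img <- ifelse(inside, spec$fg, spec$bg)
      if (spec$blur_sigma_px > 0) {
        img <- blur_axis(blur_axis(img, 1, spec$blur_sigma_px), 2, spec$blur_sigma_px)
      }
      if (spec$noise_sd > 0) {
        img <- img + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
      }
      images[[i]] <- image_stack(img, px, channel = sprintf("day%d", d))
    }
    list(images = images, truth = truth)
  })
}

#' Specification for a dot-blot array membrane phantom
#'
#' Renders a gridded antibody-array membrane: duplicate spots per target,
#' positive-reference spots at true level 1, negative-reference spots at
#' level 0, and analyte spots at known true levels on that normalized
#' scale. A global affine distortion (`gain`, `offset`) models exposure
#' and background; spot rendering is additive, then blurred and noised.
#'
#' @param layout an [array_layout()]; default [demo_array_layout()].
#' @param true_levels named numeric vector of per-target true levels on
#'   the normalized scale (positives = 1, negatives = 0); targets missing
#'   from the vector default to 0.5. Duplicate spots share their target's
#'   level by construction.
#' @param gain,offset global affine intensity transform.
#' @param blur_sigma_px,noise_sd image model.
#' @param seed integer RNG seed.
#' @return An `array_phantom_spec` list.
#' @export
array_phantom_spec <- function(layout = demo_array_layout(),
                               true_levels = NULL,
                               gain = 1, offset = 0,
                               blur_sigma_px = 1, noise_sd = 0.02,
                               seed = 1L) {
  targets <- unique(layout$spots$target[layout$spots$role == "target"])
  if (is.null(true_levels)) {
    true_levels <- setNames(
      round(seq(0.1, 1, length.out = length(targets)), 3), targets
    )
  }
  missing <- setdiff(targets, names(true_levels))
  if (length(missing) > 0) {
    true_levels[missing] <- 0.5
  }
  if (gain <= 0) abort("`gain` must be positive.")
  structure(
    list(
      layout = layout, true_levels = true_levels[targets], gain = gain,
      offset = offset, blur_sigma_px = blur_sigma_px, noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "array_phantom_spec"
  )
}

#' Generate a dot-blot membrane image with known normalized truth
#'
#' @param spec an [array_phantom_spec()].
#' @return List with `image` (an [image_stack()], pixel size 1 um for
#'   convenience — densitometry is calibration-free) and `truth`, a
#'   tibble of `target`, `true_level`.
#' @export
generate_array_membrane <- function(spec) {
  if (!inherits(spec, "array_phantom_spec")) {
    abort("`spec` must be an `array_phantom_spec`.")
  }
  lay <- spec$layout
  spots <- lay$spots
  h <- lay$image_dim[1]
  wdt <- lay$image_dim[2]
  level_of <- function(i) {
    switch(spots$role[i],
      pos = 1,
      neg = 0,
      target = unname(spec$true_levels[spots$target[i]])
    )
  }
  img <- matrix(0, h, wdt)
  yy <- matrix(seq_len(h), h, wdt)
  xx <- matrix(seq_len(wdt), h, wdt, byrow = TRUE)
  for (i in seq_len(nrow(spots))) {
    disk <- (yy - spots$cy[i])^2 + (xx - spots$cx[i])^2 <= lay$spot_radius_px^2
    img[disk] <- img[disk] + level_of(i)
  }
  with_seed(spec$seed, {
    if (spec$blur_sigma_px > 0) {
      img <- blur_axis(blur_axis(img, 1, spec$blur_sigma_px), 2, spec$blur_sigma_px)
    }
    img <- spec$offset + spec$gain * img
    if (spec$noise_sd > 0) {
      img <- img + spec$gain *
        matrix(stats::rnorm(h * wdt, 0, spec$noise_sd), h, wdt)
    }
    targets <- names(spec$true_levels)
    list(
      image = image_stack(img, 1, channel = "membrane"),
      truth = tibble(target = targets, true_level = unname(spec$true_levels))
    )
  })
}

#' Stromal seeding density from the endothelial density and cell ratio
#'
#' The endothelial density is held constant across conditions and the
#' stromal density follows from the endothelial:stromal ratio:
#' `stromal = endothelial * ratio_stroma / ratio_endo`. At 500,000
#' endothelial cells/mL this gives 250,000 (2:1), 500,000 (1:1) and
#' 1,000,000 (1:2) stromal cells/mL.
#'
#' @param endothelial_density endothelial cells per mL (> 0).
#' @param ratio_endo,ratio_stroma positive components of the
#'   endothelial:stromal ratio.
#' @return Stromal cells per mL.
#' @examples
#' stromal_density(500000, 2, 1) # 250000
#' stromal_density(500000, 1, 2) # 1e6
#' @export
stromal_density <- function(endothelial_density, ratio_endo, ratio_stroma) {
  if (endothelial_density <= 0) abort("Endothelial density must be positive.")
  if (ratio_endo <= 0 || ratio_stroma <= 0) {
    abort("Ratio components must be positive.")
  }
  endothelial_density * ratio_stroma / ratio_endo
}
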