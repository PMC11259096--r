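#' Calibrated image stacks
#'
#' An `image_stack` wraps a 2D or 3D intensity array together with its
#' physical voxel size in micrometres and a channel label. Array axes are
#' ordered `(y, x)` for 2D images and `(y, x, z)` for z-stacks, matching the
#' row/column layout of matrices returned by [tiff::readTIFF()]. Voxel
#' indices are 0-based in all physical-coordinate computations and the
#' physical coordinate of a voxel is the centre of its cell, so a straight
#' path through `n` voxels spans `n - 1` inter-centre steps.
#'
#' @param voxels numeric (or logical) array, 2D `(y, x)` or 3D `(y, x, z)`.
#' @param voxel_size_um numeric vector of per-axis voxel edge lengths in
#'   micrometres, in axis order `(y, x)` / `(y, x, z)`; a single value is
#'   recycled to all axes. All entries must be positive.
#' @param channel free-text channel label (e.g. `"CD31"`, `"laminin"`).
#' @param notes optional free-text acquisition notes.
#'
#' @return An object of class `image_stack` with elements `voxels`,
#'   `voxel_size_um` (named per axis), `channel` and `notes`.
#' @examples
#' s <- image_stack(array(0, c(8, 8, 4)), voxel_size_um = c(1, 1, 5))
#' stack_volume_mm3(s)
#' @export
image_stack <- function(voxels, voxel_size_um, channel = "unknown", notes = NULL) {
  if (is.null(dim(voxels))) {
    abort("`voxels` must be a 2D or 3D array.")
  }
  nd <- length(dim(voxels))
  if (!nd %in% c(2L, 3L)) {
    abort(sprintf("`voxels` must have 2 or 3 dimensions, not %d.", nd))
  }
  if (!all(is.finite(voxels))) {
    abort("`voxels` contains non-finite intensities.")
  }
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, nd)
  if (length(voxel_size_um) != nd) {
    abort(sprintf(
      "`voxel_size_um` must have 1 or %d entries for a %dD stack.", nd, nd
    ))
  }
  if (!all(is.finite(voxel_size_um)) || any(voxel_size_um <= 0)) {
    abort("All voxel sizes must be positive and finite (micrometres).")
  }
  names(voxel_size_um) <- c("y", "x", "z")[seq_len(nd)]
  structure(
    list(
      voxels = voxels,
      voxel_size_um = voxel_size_um,
      channel = as.character(channel)[1],
      notes = notes
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %s voxels (%s), voxel size %s um, channel '%s'\n",
    paste(d, collapse = " x "),
    if (is.logical(x$voxels)) "binary" else "intensity",
    paste(signif(x$voxel_size_um, 4), collapse = " x "),
    x$channel
  ))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

is_image_stack <- function(x) inherits(x, "image_stack")

assert_stack <- function(x, arg = "stack") {
  if (!is_image_stack(x)) abort(sprintf("`%s` must be an `image_stack`.", arg))
  invisible(x)
}

as_3d <- function(a) {
  if (length(dim(a)) == 2L) array(a, c(dim(a), 1L)) else a
}

#' Rectangular region of interest
#'
#' Axis-aligned bounds in voxel indices. Intervals are half-open on the
#' 1-based R indexing convention: voxels `from[i] .. to[i]` inclusive are
#' selected, and the ROI must be non-empty and lie inside the stack.
#'
#' @param from,to integer vectors of per-axis start and end voxel indices
#'   (1-based, inclusive), one entry per stack axis.
#' @return An object of class `stack_roi`.
#' @export
stack_roi <- function(from, to) {
  from <- as.integer(from)
  to <- as.integer(to)
  if (length(from) != length(to)) abort("`from` and `to` must have equal length.")
  if (any(from < 1L) || any(to < from)) {
    abort("ROI bounds must satisfy 1 <= from <= to on every axis.")
  }
  structure(list(from = from, to = to), class = "stack_roi")
}

roi_in_stack <- function(roi, stack) {
  d <- dim(stack$voxels)
  if (length(roi$from) != length(d)) {
    abort("ROI dimensionality does not match the stack.")
  }
  if (any(roi$to > d)) abort("ROI exceeds the stack bounds.")
  invisible(roi)
}

#' Crop a stack to an ROI
#'
#' @param stack an [image_stack()].
#' @param roi a [stack_roi()].
#' @return The cropped `image_stack` (calibration unchanged).
#' @export
crop_stack <- function(stack, roi) {
  assert_stack(stack)
  roi_in_stack(roi, stack)
  idx <- Map(seq.int, roi$from, roi$to)
  v <- do.call(`[`, c(list(stack$voxels), idx, list(drop = FALSE)))
  image_stack(v, stack$voxel_size_um, stack$channel, stack$notes)
}

#' Physical volume of a stack or ROI in cubic millimetres
#'
#' The volume is the voxel count times the voxel volume,
#' `prod(dim) * prod(voxel_size_um)` in um^3, converted to mm^3
#' (1 mm^3 = 1e9 um^3). For a 2D image the "volume" is the area in mm^2
#' times nothing — a 2D input is an error; use [pixel_area_mm2()] instead.
#'
#' @param stack a calibrated 3D [image_stack()].
#' @param roi optional [stack_roi()] restricting the volume.
#' @return Volume in mm^3 (scalar).
#' @examples
#' s <- image_stack(array(0, c(10, 10, 10)), 1)
#' stack_volume_mm3(s) # 1e-6
#' @export
stack_volume_mm3 <- function(stack, roi = NULL) {
  assert_stack(stack)
  if (length(dim(stack$voxels)) != 3L) {
    abort("`stack_volume_mm3()` requires a 3D stack.")
  }
  if (!is.null(roi)) {
    roi_in_stack(roi, stack)
    n_vox <- prod(roi$to - roi$from + 1L)
  } else {
    n_vox <- prod(dim(stack$voxels))
  }
  n_vox * prod(stack$voxel_size_um) / 1e9
}

#' Physical area of one pixel in square millimetres
#'
#' @param pixel_size_um pixel edge length(s) in micrometres (length 1 or 2).
#' @return Area of a single pixel in mm^2.
#' @export
pixel_area_mm2 <- function(pixel_size_um) {
  if (length(pixel_size_um) == 1L) pixel_size_um <- rep(pixel_size_um, 2L)
  if (any(pixel_size_um <= 0)) abort("Pixel sizes must be positive.")
  prod(pixel_size_um[1:2]) / 1e6
}

calibration_sidecar <- function(path) paste0(path, ".json")

#' Write a calibrated stack as multi-page TIFF plus JSON sidecar
#'
#' Intensities are rescaled to `[0, 1]` for TIFF storage using the range
#' recorded in the sidecar, so the round trip through [read_stack()]
#' restores the original values (up to 16-bit quantization). Voxel size,
#' channel and intensity range travel in `<path>.json`.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  assert_stack(stack)
  v <- as_3d(stack$voxels * 1.0)
  rng <- range(v)
  scaled <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  pages <- lapply(seq_len(dim(scaled)[3]), function(z) scaled[, , z])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    voxel_size_um = as.list(stack$voxel_size_um),
    channel = stack$channel,
    intensity_range = rng,
    ndim = length(dim(stack$voxels))
  )
  jsonlite::write_json(meta, calibration_sidecar(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a calibrated stack from TIFF
#'
#' Calibration is taken from the JSON sidecar written by [write_stack()]
#' when present; an explicit `voxel_size_um` always overrides it. A file
#' with neither sidecar calibration nor an override is an error: lengths
#' and volumes are meaningless without physical pixel sizes.
#'
#' @param path TIFF path.
#' @param voxel_size_um optional per-axis calibration override
#'   (micrometres).
#' @param channel optional channel label override.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, voxel_size_um = NULL, channel = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1] else p # drop extra channels
  })
  v <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  meta <- NULL
  sc <- calibration_sidecar(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!is.null(meta$intensity_range)) {
    rng <- as.numeric(meta$intensity_range)
    if (diff(rng) > 0) v <- v * diff(rng) + rng[1] else v <- v * 0 + rng[1]
  }
  if (!is.null(meta$ndim) && meta$ndim == 2L && dim(v)[3] == 1L) {
    v <- v[, , 1, drop = TRUE]
  }
  vs <- voxel_size_um
  if (is.null(vs) && !is.null(meta$voxel_size_um)) {
    vs <- unlist(meta$voxel_size_um)
  }
  # a single-page file with a 2D calibration override is a 2D image
  if (is.null(meta) && length(vs) == 2L && length(dim(v)) == 3L && dim(v)[3] == 1L) {
    v <- v[, , 1, drop = TRUE]
  }
  if (is.null(vs)) {
    abort(paste0(
      "No calibration: `", path, "` has no sidecar voxel size and no ",
      "`voxel_size_um` override was given."
    ))
  }
  ch <- channel %||% meta$channel %||% "unknown"
  image_stack(v, vs, channel = ch)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
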