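#' Spheroid outgrowth area in square millimetres
#'
#' Measures the total outgrowth area (spheroid body included) of a 2D
#' image. In `"threshold_auto"` mode the image is Otsu-thresholded and
#' the largest 8-connected foreground component is measured — suitable
#' for phantoms and high-contrast images. Manually traced masks are
#' first-class inputs (`"manual_mask"`), reproducing a hand-tracing
#' workflow verbatim.
#'
#' @param image a calibrated 2D [image_stack()], or (for
#'   `"manual_mask"`) a logical matrix / binary `image_stack`.
#' @param pixel_size_um pixel size override in micrometres; defaults to
#'   the stack calibration.
#' @param method `"threshold_auto"` or `"manual_mask"`.
#' @return Area in mm^2 (scalar).
#' @examples
#' m <- matrix(FALSE, 120, 120); m[30:90, 30:90] <- TRUE
#' outgrowth_area(m, pixel_size_um = 1, method = "manual_mask")
#' @export
outgrowth_area <- function(image, pixel_size_um = NULL,
                           method = c("threshold_auto", "manual_mask")) {
  method <- match.arg(method)
  if (is_image_stack(image)) {
    if (is.null(pixel_size_um)) pixel_size_um <- image$voxel_size_um
    img <- image$voxels
  } else {
    img <- image
  }
  if (is.null(pixel_size_um)) {
    abort("`pixel_size_um` is required when `image` carries no calibration.")
  }
  if (length(dim(img)) != 2L) abort("`image` must be 2D.")
  if (method == "manual_mask") {
    if (!is.logical(img)) abort("A manual mask must be logical.")
    n_px <- sum(img)
    if (n_px == 0) abort("The manual mask is empty.")
    return(n_px * pixel_area_mm2(pixel_size_um))
  }
  s <- image_stack(img * 1.0, pixel_size_um)
  mask <- binarize(s, "otsu_global")$voxels
  if (!any(mask)) abort("No foreground detected.")
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  max(sizes) * pixel_area_mm2(pixel_size_um)
}

#' Average replicate trace measurements of one outgrowth
#'
#' @param areas numeric vector of 1 to 3 positive traced areas (mm^2).
#' @return Their arithmetic mean.
#' @export
average_traces <- function(areas) {
  if (length(areas) < 1) abort("At least one traced area is required.")
  if (length(areas) > 3) abort("At most three traces are averaged.")
  if (any(!is.finite(areas)) || any(areas <= 0)) {
    abort("Traced areas must be positive.")
  }
  mean(areas)
}

#' Fold change of spheroid outgrowth area relative to day 0
#'
#' `(area_day_d - area_day0) / area_day0`: the dimensionless relative
#' growth of the outgrowth area since encapsulation. It is invariant to
#' a common rescaling of both areas and is at least -1 for non-negative
#' areas.
#'
#' @param area_day_d outgrowth area on the later day (mm^2).
#' @param area_day0 outgrowth area on day 0 (mm^2, > 0).
#' @return Fold change (scalar or vector).
#' @examples
#' fold_change(2, 1) # 1
#' fold_change(1, 1) # 0
#' @export
fold_change <- function(area_day_d, area_day0) {
  if (any(!is.finite(area_day0)) || any(area_day0 <= 0)) {
    abort("`area_day0` must be positive.")
  }
  (area_day_d - area_day0) / area_day0
}

#' Per-spheroid areas and fold changes from an observation table
#'
#' Takes a tidy table of traced areas (up to three replicate traces per
#' spheroid and day), averages the traces, and appends the fold change
#' of each day relative to the same spheroid's day 0.
#'
#' @param observations data frame with columns `spheroid`, `day`, `area_mm2`
#'   (one row per trace) and optionally `condition`.
#' @return Tibble with one row per spheroid and day: mean area and
#'   `fold_change` (NA when the spheroid has no day-0 row).
#' @export
spheroid_fold_changes <- function(observations) {
  req <- c("spheroid", "day", "area_mm2")
  if (!all(req %in% names(observations))) {
    abort("`observations` needs columns spheroid, day, area_mm2.")
  }
  grp <- intersect(c("condition", "spheroid", "day"), names(observations))
  out <- observations |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(area_mm2 = average_traces(.data$area_mm2), .groups = "drop_last") |>
    dplyr::mutate(
      fold_change = if (any(.data$day == 0)) {
        fold_change(.data$area_mm2, .data$area_mm2[.data$day == 0][1])
      } else {
        NA_real_
      }
    ) |>
    dplyr::ungroup()
  as_tibble(out)
}
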