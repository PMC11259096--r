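#' Average voxel intensity of a stack, optionally under a mask
#'
#' @param stack an [image_stack()].
#' @param mask optional binary [image_stack()] (or logical array) of the
#'   same shape; when given, the mean is taken over mask voxels only.
#' @return Mean intensity (scalar).
#' @export
average_intensity <- function(stack, mask = NULL) {
  assert_stack(stack)
  if (is.null(mask)) return(mean(stack$voxels))
  m <- if (is_image_stack(mask)) mask$voxels else mask
  if (!is.logical(m)) abort("`mask` must be logical.")
  if (!identical(dim(m), dim(stack$voxels))) {
    abort("`mask` shape does not match the stack.")
  }
  if (!any(m)) abort("`mask` is empty.")
  mean(stack$voxels[m])
}

#' Binary-mask colocalization (degree of overlap)
#'
#' The overlap statistic is the voxel-wise product of the two binarized
#' matrices: `n_intersection = sum(A * B)`. Because the denominator
#' convention matters and is easy to leave implicit, all three are
#' reported: the fraction of A covered by B (the headline "degree of
#' overlap" when A is the vessel mask and B the protein mask), the
#' fraction of B covered by A, and the Jaccard index. Intensity-weighted
#' coefficients (Pearson, Manders on intensities) are out of scope; the
#' statistic is mask-based by design.
#'
#' @param mask_a,mask_b binary [image_stack()]s or logical arrays of
#'   identical shape. By convention A is the vessel (e.g. CD31) mask and
#'   B the protein (e.g. laminin, ZO-1) mask.
#' @return One-row tibble: `n_a`, `n_b`, `n_intersection`,
#'   `fraction_over_a`, `fraction_over_b`, `jaccard`. Fractions with an
#'   empty denominator are `NA` (an empty A makes `fraction_over_a`
#'   undefined).
#' @examples
#' a <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
#' b <- array(c(TRUE, FALSE, TRUE, FALSE), c(2, 2, 1))
#' mask_overlap(a, b)$fraction_over_a # 0.5
#' @export
mask_overlap <- function(mask_a, mask_b) {
  a <- if (is_image_stack(mask_a)) mask_a$voxels else mask_a
  b <- if (is_image_stack(mask_b)) mask_b$voxels else mask_b
  if (!is.logical(a) || !is.logical(b)) abort("Masks must be logical.")
  if (!identical(dim(a), dim(b))) abort("Masks must have the same shape.")
  n_a <- sum(a)
  n_b <- sum(b)
  n_i <- sum(a & b) # == sum(A * B), the binarized matrix product
  n_u <- n_a + n_b - n_i
  tibble(
    n_a = n_a, n_b = n_b, n_intersection = n_i,
    fraction_over_a = if (n_a > 0) n_i / n_a else NA_real_,
    fraction_over_b = if (n_b > 0) n_i / n_b else NA_real_,
    jaccard = if (n_u > 0) n_i / n_u else NA_real_
  )
}
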