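#' Dot-blot array layout
#'
#' Describes a gridded antibody-array membrane: spot centres in pixels,
#' the target each spot reports (arrays print each target as a duplicate
#' spot pair), and which spots are positive / negative reference spots.
#' The layout is user-supplied configuration, never hard-coded, so any
#' membrane geometry can be quantified.
#'
#' @param spots data frame with columns `spot` (id), `cy`, `cx` (centre
#'   pixel coordinates), `target` (name; shared by duplicates) and
#'   `role` (`"target"`, `"pos"` or `"neg"`).
#' @param spot_radius_px radius of the quantification disk in pixels
#'   (0 reads the single centre pixel).
#' @param image_dim expected image size `(height, width)` in pixels.
#' @return An `array_layout` object.
#' @export
array_layout <- function(spots, spot_radius_px, image_dim) {
  req <- c("spot", "cy", "cx", "target", "role")
  if (!all(req %in% names(spots))) {
    abort("`spots` needs columns spot, cy, cx, target, role.")
  }
  if (!all(spots$role %in% c("target", "pos", "neg"))) {
    abort("`role` must be one of 'target', 'pos', 'neg'.")
  }
  if (!any(spots$role == "pos") || !any(spots$role == "neg")) {
    abort("The layout must contain positive and negative reference spots.")
  }
  if (spot_radius_px < 0) abort("`spot_radius_px` must be >= 0.")
  # overlapping spots make per-spot densities ambiguous
  if (nrow(spots) > 1) {
    dmin <- min(stats::dist(cbind(spots$cy, spots$cx)))
    if (dmin < 2 * spot_radius_px) {
      abort("Spot disks overlap; shrink `spot_radius_px` or respace the grid.")
    }
  }
  structure(
    list(
      spots = as_tibble(spots), spot_radius_px = spot_radius_px,
      image_dim = as.integer(image_dim)
    ),
    class = "array_layout"
  )
}

#' A small demonstration membrane layout
#'
#' Four rows by ten columns on a 16-pixel pitch; horizontally adjacent
#' spots are duplicates of the same target. Three duplicate pairs are
#' positive references, one pair is the negative reference, and the
#' remaining 16 pairs carry targets `T01`..`T16`.
#'
#' @param pitch_px grid pitch in pixels.
#' @param spot_radius_px spot radius in pixels.
#' @return An [array_layout()].
#' @export
demo_array_layout <- function(pitch_px = 16, spot_radius_px = 4) {
  rows <- 4L
  cols <- 10L
  grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  grid <- grid[order(grid$row, grid$col), ]
  pair <- (seq_len(nrow(grid)) + 1L) %/% 2L
  role <- rep("target", nrow(grid))
  role[pair %in% c(1L, 10L, 11L)] <- "pos"
  role[pair == 20L] <- "neg"
  target_ids <- setdiff(unique(pair), c(1L, 10L, 11L, 20L))
  tname <- setNames(sprintf("T%02d", seq_along(target_ids)), target_ids)
  target <- ifelse(role == "target", tname[as.character(pair)],
    ifelse(role == "pos", "positive_control", "negative_control")
  )
  spots <- tibble(
    spot = seq_len(nrow(grid)),
    cy = grid$row * pitch_px,
    cx = grid$col * pitch_px,
    target = unname(target),
    role = role
  )
  array_layout(spots, spot_radius_px,
    image_dim = c((rows + 1L) * pitch_px, (cols + 1L) * pitch_px)
  )
}

#' Raw spot densitometry
#'
#' Reads the mean pixel intensity within a disk of the layout radius at
#' each spot centre (radius 0 reads the single centre pixel).
#'
#' @param image 2D [image_stack()] or numeric matrix of the membrane.
#' @param layout an [array_layout()].
#' @return Tibble: `spot`, `target`, `role`, `raw_density`.
#' @export
quantify_spots <- function(image, layout) {
  img <- if (is_image_stack(image)) image$voxels else image
  if (length(dim(img)) != 2L) abort("`image` must be 2D.")
  if (!inherits(layout, "array_layout")) abort("`layout` must be an `array_layout`.")
  h <- nrow(img)
  w <- ncol(img)
  r <- layout$spot_radius_px
  sp <- layout$spots
  if (any(sp$cy - r < 1 | sp$cy + r > h | sp$cx - r < 1 | sp$cx + r > w)) {
    abort("A spot disk extends beyond the image bounds.")
  }
  dens <- vapply(seq_len(nrow(sp)), function(i) {
    ys <- seq.int(floor(sp$cy[i] - r), ceiling(sp$cy[i] + r))
    xs <- seq.int(floor(sp$cx[i] - r), ceiling(sp$cx[i] + r))
    sub <- img[ys, xs, drop = FALSE]
    dy <- matrix(ys - sp$cy[i], length(ys), length(xs))
    dx <- matrix(xs - sp$cx[i], length(ys), length(xs), byrow = TRUE)
    disk <- dy^2 + dx^2 <= r^2
    mean(sub[disk])
  }, numeric(1))
  tibble(spot = sp$spot, target = sp$target, role = sp$role, raw_density = dens)
}

#' Reference-normalized spot densities
#'
#' Duplicate spots of each target are averaged; the mean negative-control
#' density is subtracted; the result is scaled by the reference span.
#' With `positive_only = FALSE` (default) the divisor is
#' `mean(pos) - mean(neg)`, which makes the normalized values exactly
#' invariant to any global affine intensity transform (gain and offset —
#' exposure changes cancel). With `positive_only = TRUE` the divisor is
#' the raw positive-control mean (background subtraction of samples
#' only), the convention of normalizing straight to the positive-control
#' density.
#'
#' @param raw tibble from [quantify_spots()] (columns `target`, `role`,
#'   `raw_density`).
#' @param positive_only divide by the raw positive mean instead of the
#'   positive-minus-negative span.
#' @return Tibble with one row per target: `target`, `mean_density`,
#'   `normalized_density`. Reference rows are included
#'   (`positive_control` normalizes to 1, `negative_control` to 0 in
#'   span mode).
#' @export
normalize_spots <- function(raw, positive_only = FALSE) {
  req <- c("target", "role", "raw_density")
  if (!all(req %in% names(raw))) {
    abort("`raw` needs columns target, role, raw_density.")
  }
  pos <- mean(raw$raw_density[raw$role == "pos"])
  neg <- mean(raw$raw_density[raw$role == "neg"])
  if (!is.finite(pos) || !is.finite(neg)) {
    abort("Positive and negative reference spots are required.")
  }
  if (pos <= neg) {
    abort("Positive-control density does not exceed the negative control; the membrane is saturated or mis-laid-out.")
  }
  div <- if (positive_only) pos else pos - neg
  raw |>
    dplyr::group_by(.data$target, .data$role) |>
    dplyr::summarise(mean_density = mean(.data$raw_density), .groups = "drop") |>
    dplyr::mutate(normalized_density = (.data$mean_density - neg) / div) |>
    dplyr::arrange(.data$role, .data$target)
}

#' Quantify a membrane image end to end
#'
#' @param image membrane image (2D).
#' @param layout an [array_layout()].
#' @param positive_only see [normalize_spots()].
#' @param membrane optional membrane id added as a column.
#' @return Normalized density tibble (see [normalize_spots()]).
#' @export
quantify_membrane <- function(image, layout, positive_only = FALSE, membrane = NULL) {
  out <- normalize_spots(quantify_spots(image, layout), positive_only)
  if (!is.null(membrane)) out <- dplyr::mutate(out, membrane = membrane, .before = 1)
  out
}

#' Summary statistics of a protein-interaction graph
#'
#' Consumes a user-supplied undirected edge list (e.g. exported from an
#' interaction database) and reports node count, edge count, average
#' node degree (`2 * E / N`) and the mean local clustering coefficient
#' over nodes, with degree-<2 nodes contributing 0. A 14-node, 25-edge
#' network has average degree 50/14 = 3.57.
#'
#' @param edges two-column data frame (or matrix) of node-name pairs;
#'   duplicate edges are collapsed after canonicalization and self-loops
#'   are rejected.
#' @param nodes optional character vector of node names to include even
#'   if isolated (degree 0).
#' @return One-row tibble: `n_nodes`, `n_edges`, `avg_degree`,
#'   `avg_clustering`.
#' @examples
#' tri <- data.frame(a = c("A", "B", "C"), b = c("B", "C", "A"))
#' interaction_graph_summary(tri) # degree 2, clustering 1
#' @export
interaction_graph_summary <- function(edges, nodes = NULL) {
  e <- as.data.frame(edges)
  if (ncol(e) < 2) abort("`edges` must have two columns.")
  a <- as.character(e[[1]])
  b <- as.character(e[[2]])
  if (any(a == b)) abort("Self-loops are not allowed in the interaction graph.")
  g <- igraph::graph_from_data_frame(
    unique(data.frame(a = pmin(a, b), b = pmax(a, b))),
    directed = FALSE,
    vertices = if (is.null(nodes)) NULL else unique(c(nodes, a, b))
  )
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  tibble(
    n_nodes = n, n_edges = m,
    avg_degree = if (n > 0) 2 * m / n else NA_real_,
    avg_clustering = if (n > 0) mean(cl) else NA_real_
  )
}
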