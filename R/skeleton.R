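#' 3D skeletonization of a vessel mask
#'
#' Topology-preserving curve thinning in the (26, 6) digital topology:
#' simple border voxels are deleted in six directional sub-iterations,
#' with sequential re-checking so connectivity is never broken, until the
#' mask is one voxel wide. Voxels with a single foreground neighbour
#' (curve endpoints) are protected, so vessel ends do not erode beyond
#' the tube cap. The number of 26-connected components is preserved; an
#' empty mask yields an empty skeleton.
#'
#' @param mask a binary [image_stack()] (2D inputs are treated as a
#'   single-slice volume).
#' @return A binary `image_stack` containing the skeleton.
#' @export
skeletonize <- function(mask) {
  assert_stack(mask, "mask")
  if (!is.logical(mask$voxels)) abort("`mask` must be binary (logical voxels).")
  d2 <- length(dim(mask$voxels)) == 2L
  a <- as_3d(mask$voxels)
  sk <- .thin3d_cpp(a, dim(a))
  if (d2) sk <- sk[, , 1]
  res <- image_stack(sk, mask$voxel_size_um, mask$channel, mask$notes)
  res$provenance <- c(mask$provenance, list(skeletonized = TRUE))
  res
}

neighbor_offsets26 <- function() {
  g <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  as.matrix(g[!(g$dy == 0 & g$dx == 0 & g$dz == 0), ])
}

# Build the skeleton graph from the voxel set once (no pruning).
build_graph_once <- function(v, voxel_size_um) {
  d <- dim(v)
  idx <- which(v)
  n <- length(idx)
  empty_graph <- function() {
    list(
      nodes = tibble(
        node = integer(0), kind = character(0), degree = integer(0),
        y_um = numeric(0), x_um = numeric(0), z_um = numeric(0),
        component = integer(0)
      ),
      segments = tibble(
        segment = integer(0), node_from = integer(0), node_to = integer(0),
        length_um = numeric(0), n_voxels = integer(0), component = integer(0),
        cyclic = logical(0)
      ),
      paths = list(), n_components = 0L
    )
  }
  if (n == 0) return(empty_graph())

  coords <- arrayInd(idx, d)
  pos <- integer(prod(d))
  pos[idx] <- seq_len(n)
  offs <- neighbor_offsets26()
  # neighbour table: nbr[i, k] = index (1..n) of the k-th neighbour of voxel i, 0 if none
  nbr <- matrix(0L, n, 26)
  for (k in seq_len(26)) {
    yy <- coords[, 1] + offs[k, 1]
    xx <- coords[, 2] + offs[k, 2]
    zz <- coords[, 3] + offs[k, 3]
    ok <- yy >= 1 & yy <= d[1] & xx >= 1 & xx <= d[2] & zz >= 1 & zz <= d[3]
    lin <- yy[ok] + d[1] * (xx[ok] - 1) + d[1] * d[2] * (zz[ok] - 1)
    hit <- pos[lin]
    col <- integer(n)
    col[ok] <- hit
    nbr[, k] <- col
  }
  degree <- rowSums(nbr > 0)
  nbr_list <- lapply(seq_len(n), function(i) nbr[i, nbr[i, ] > 0])

  comp <- label_components(v)
  comp_of <- comp[idx]
  n_components <- max(comp_of)

  kind_vox <- ifelse(degree == 1, "endpoint",
    ifelse(degree >= 3, "junction", ifelse(degree == 0, "isolated", "slab"))
  )

  # Merge touching junction voxels into single junction nodes
  node_of <- integer(n)
  node_kind <- character(0)
  node_coord <- matrix(numeric(0), ncol = 3)
  node_comp <- integer(0)
  next_node <- 0L
  junc <- which(kind_vox == "junction")
  seen <- logical(n)
  phys <- sweep(coords - 1, 2, voxel_size_um, `*`)
  for (s in junc) {
    if (seen[s]) next
    next_node <- next_node + 1L
    stack <- s
    seen[s] <- TRUE
    members <- integer(0)
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, cur)
      node_of[cur] <- next_node
      for (u in nbr_list[[cur]]) {
        if (!seen[u] && kind_vox[u] == "junction") {
          seen[u] <- TRUE
          stack <- c(stack, u)
        }
      }
    }
    node_kind <- c(node_kind, "junction")
    node_coord <- rbind(node_coord, colMeans(phys[members, , drop = FALSE]))
    node_comp <- c(node_comp, comp_of[members[1]])
  }
  for (s in which(kind_vox %in% c("endpoint", "isolated"))) {
    next_node <- next_node + 1L
    node_of[s] <- next_node
    node_kind <- c(node_kind, kind_vox[s])
    node_coord <- rbind(node_coord, phys[s, ])
    node_comp <- c(node_comp, comp_of[s])
  }

  step_len <- function(i, j) {
    sqrt(sum(((coords[i, ] - coords[j, ]) * voxel_size_um)^2))
  }
  # Polygonal chord through every other path voxel: per-voxel stepping
  # overestimates the length of oblique centrelines by the staircase
  # effect; a stride-2 chord (endpoints always included) largely cancels it.
  path_len <- function(p) {
    if (length(p) < 2) return(0)
    ks <- unique(c(seq(1, length(p), by = 2), length(p)))
    sum(vapply(seq_len(length(ks) - 1), function(k) {
      step_len(p[ks[k]], p[ks[k + 1]])
    }, numeric(1)))
  }

  seg_from <- integer(0)
  seg_to <- integer(0)
  seg_len <- numeric(0)
  seg_nvox <- integer(0)
  seg_comp <- integer(0)
  seg_cyclic <- logical(0)
  paths <- list()
  visited <- logical(n) # interior (slab) voxels consumed by a trace
  is_node_vox <- node_of > 0

  add_seg <- function(from, to, path, cyclic = FALSE) {
    seg_from <<- c(seg_from, from)
    seg_to <<- c(seg_to, to)
    seg_len <<- c(seg_len, path_len(path) + if (cyclic) step_len(path[length(path)], path[1]) else 0)
    seg_nvox <<- c(seg_nvox, length(path))
    seg_comp <<- c(seg_comp, comp_of[path[1]])
    seg_cyclic <<- c(seg_cyclic, cyclic)
    paths[[length(paths) + 1]] <<- phys[path, , drop = FALSE]
  }

  for (i in which(is_node_vox & kind_vox != "isolated")) {
    for (u in nbr_list[[i]]) {
      if (is_node_vox[u]) {
        if (node_of[u] == node_of[i]) next # same junction cluster
        if (i < u) add_seg(node_of[i], node_of[u], c(i, u))
      } else if (!visited[u]) {
        # walk the degree-2 chain
        path <- c(i, u)
        visited[u] <- TRUE
        prev <- i
        cur <- u
        repeat {
          nxt <- nbr_list[[cur]]
          nxt <- nxt[nxt != prev]
          if (length(nxt) == 0) break # dangling (should not happen on a skeleton)
          # prefer a node voxel terminus; otherwise continue along the chain
          nd <- nxt[is_node_vox[nxt]]
          if (length(nd) > 0) {
            # avoid immediately re-entering the start cluster through a diagonal
            nd_keep <- nd[!(node_of[nd] == node_of[i] & length(path) == 2)]
            term <- if (length(nd_keep) > 0) nd_keep[1] else nd[1]
            path <- c(path, term)
            add_seg(node_of[i], node_of[term], path)
            break
          }
          nxt <- nxt[!visited[nxt]]
          if (length(nxt) == 0) break
          prev <- cur
          cur <- nxt[1]
          visited[cur] <- TRUE
          path <- c(path, cur)
        }
      }
    }
  }

  # Pure cycles: leftover unvisited slab voxels with no node voxel anywhere
  for (s in which(kind_vox == "slab" & !visited & !is_node_vox)) {
    if (visited[s]) next
    path <- s
    visited[s] <- TRUE
    prev <- s
    cur <- nbr_list[[s]][1]
    while (!is.na(cur) && !visited[cur]) {
      visited[cur] <- TRUE
      path <- c(path, cur)
      nxt <- nbr_list[[cur]]
      nxt <- nxt[nxt != prev]
      prev <- cur
      cur <- if (length(nxt) > 0) nxt[1] else NA_integer_
    }
    add_seg(NA_integer_, NA_integer_, path, cyclic = TRUE)
  }

  nodes <- tibble(
    node = seq_len(next_node), kind = node_kind,
    degree = vapply(seq_len(next_node), function(nd) {
      sum(seg_from == nd, na.rm = TRUE) + sum(seg_to == nd, na.rm = TRUE)
    }, numeric(1)),
    y_um = node_coord[, 1], x_um = node_coord[, 2], z_um = node_coord[, 3],
    component = node_comp
  )
  segments <- tibble(
    segment = seq_along(seg_len), node_from = seg_from, node_to = seg_to,
    length_um = seg_len, n_voxels = seg_nvox, component = seg_comp,
    cyclic = seg_cyclic
  )
  list(
    nodes = nodes, segments = segments, paths = paths,
    n_components = n_components
  )
}

#' Build the skeleton graph of a thinned mask
#'
#' Classifies skeleton voxels by their number of 26-neighbours
#' (1 = endpoint, 2 = chain, >= 3 = junction), merges touching junction
#' voxels into single junction nodes (cluster centroid as the node
#' coordinate), and extracts segments as maximal chains between nodes.
#' Segment length is the sum of physical centre-to-centre steps along the
#' voxel path, so anisotropic z-steps and diagonal moves are measured
#' correctly. A closed ring with no node voxel becomes one cyclic segment
#' with no endpoints. Spur segments (one endpoint end) shorter than
#' `prune_um` are removed and the graph rebuilt, which suppresses
#' thinning artefacts near junctions; pruning is recorded in the result.
#'
#' @param skeleton a binary [image_stack()] holding a 1-voxel-wide
#'   skeleton (from [skeletonize()]).
#' @param prune_um prune spurs shorter than this length (um); 0 disables.
#' @return An object of class `skeleton_graph`: list with tibbles
#'   `nodes` (`node`, `kind`, `degree`, physical coordinates,
#'   `component`) and `segments` (`segment`, end nodes, `length_um`,
#'   `n_voxels`, `component`, `cyclic`), the ordered physical `paths`,
#'   `n_components`, `voxel_size_um` and `pruned_segments`.
#' @export
build_skeleton_graph <- function(skeleton, prune_um = 3) {
  assert_stack(skeleton, "skeleton")
  if (!is.logical(skeleton$voxels)) abort("`skeleton` must be binary.")
  v <- as_3d(skeleton$voxels)
  vs <- skeleton$voxel_size_um
  if (length(vs) == 2L) vs <- c(vs, z = 1)

  # flag thick (non-skeleton) regions: any fully-foreground 2x2x2 block
  d <- dim(v)
  if (all(d >= 2)) {
    blk <- v[-d[1], -d[2], -d[3], drop = FALSE] & v[-1, -d[2], -d[3], drop = FALSE] &
      v[-d[1], -1, -d[3], drop = FALSE] & v[-1, -1, -d[3], drop = FALSE] &
      v[-d[1], -d[2], -1, drop = FALSE] & v[-1, -d[2], -1, drop = FALSE] &
      v[-d[1], -1, -1, drop = FALSE] & v[-1, -1, -1, drop = FALSE]
    if (any(blk)) {
      warn("Input contains thick (2x2x2) regions; run skeletonize() first.")
    }
  }

  pruned <- 0L
  g <- build_graph_once(v, vs)
  if (prune_um > 0) {
    for (iter in 1:10) {
      if (nrow(g$segments) == 0) break
      endp <- g$nodes$node[g$nodes$kind == "endpoint"]
      # spurs: short segments with an endpoint end, in components that have
      # other segments (never prune an isolated short vessel away)
      seg <- g$segments
      comp_sizes <- table(seg$component)
      spur <- !seg$cyclic & seg$length_um < prune_um &
        (seg$node_from %in% endp | seg$node_to %in% endp) &
        as.integer(comp_sizes[as.character(seg$component)]) > 1
      if (!any(spur)) break
      # remove spur voxels (keep the junction-end voxel)
      for (si in which(spur)) {
        p <- g$paths[[si]]
        vox <- round(sweep(p, 2, vs, `/`)) + 1
        ends <- c(seg$node_from[si], seg$node_to[si])
        drop_last <- g$nodes$kind[ends[2]] != "endpoint"
        drop_first <- g$nodes$kind[ends[1]] != "endpoint"
        rows <- seq_len(nrow(vox))
        if (drop_last) rows <- rows[-length(rows)]
        if (drop_first && length(rows) > 0) rows <- rows[-1]
        for (ri in rows) {
          v[vox[ri, 1], vox[ri, 2], vox[ri, 3]] <- FALSE
        }
        pruned <- pruned + 1L
      }
      g <- build_graph_once(v, vs)
    }
  }
  structure(
    c(g, list(voxel_size_um = vs, prune_um = prune_um, pruned_segments = pruned)),
    class = "skeleton_graph"
  )
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "<skeleton_graph> %d nodes (%d junctions, %d endpoints), %d segments, %d component(s), total length %.1f um\n",
    nrow(x$nodes), sum(x$nodes$kind == "junction"),
    sum(x$nodes$kind == "endpoint"), nrow(x$segments), x$n_components,
    sum(x$segments$length_um)
  ))
  invisible(x)
}

#' Vessel-network morphometrics from a skeleton graph
#'
#' The reported metrics follow the convention that a "vessel" is a
#' skeleton segment between nodes of degree not equal to 2 (so average
#' branch length is total network length divided by the number of
#' vessels), and "branches" are branch points plus endpoints. Length
#' density is micrometres of vessel per cubic millimetre of gel.
#'
#' @param graph a [build_skeleton_graph()] result.
#' @param volume_mm3 imaged physical volume in mm^3 (> 0), typically
#'   [stack_volume_mm3()].
#' @return One-row tibble: `total_length_um`, `total_length_per_mm3`,
#'   `n_vessels`, `n_branch_points`, `n_endpoints`, `n_branches`,
#'   `avg_branch_length_um` (`NA` when there are no vessels),
#'   `n_components`.
#' @export
measure_network <- function(graph, volume_mm3) {
  if (!inherits(graph, "skeleton_graph")) {
    abort("`graph` must be a `skeleton_graph`.")
  }
  if (!is.numeric(volume_mm3) || volume_mm3 <= 0) {
    abort("`volume_mm3` must be positive.")
  }
  total <- sum(graph$segments$length_um)
  nv <- nrow(graph$segments)
  nbp <- sum(graph$nodes$kind == "junction")
  nep <- sum(graph$nodes$kind == "endpoint")
  tibble(
    total_length_um = total,
    total_length_per_mm3 = total / volume_mm3,
    n_vessels = nv,
    n_branch_points = nbp,
    n_endpoints = nep,
    n_branches = nbp + nep,
    avg_branch_length_um = if (nv > 0) total / nv else NA_real_,
    n_components = graph$n_components
  )
}

#' Segment a mask and measure its network in one call
#'
#' @param mask a binary [image_stack()].
#' @param prune_um spur-prune length passed to [build_skeleton_graph()].
#' @param volume_mm3 physical volume; defaults to the full stack volume.
#' @return One-row tibble of network metrics (see [measure_network()]).
#' @export
measure_mask <- function(mask, prune_um = 3, volume_mm3 = stack_volume_mm3(mask)) {
  g <- build_skeleton_graph(skeletonize(mask), prune_um = prune_um)
  measure_network(g, volume_mm3)
}

#' Average network metrics across the ROIs of one hydrogel
#'
#' Multiple regions of interest imaged in the same gel are summarized by
#' the unweighted arithmetic mean of each metric, one row in, one row
#' out, order-invariant.
#'
#' @param metrics tibble of per-ROI metric rows (as from
#'   [measure_network()]).
#' @return One-row tibble of averaged metrics.
#' @export
average_rois <- function(metrics) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0) {
    abort("`metrics` must contain at least one ROI row.")
  }
  dplyr::summarise(metrics, dplyr::across(dplyr::where(is.numeric), mean))
}
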