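# Shared fixtures, all generated in code.

# A tiny calibrated stack with reproducible intensities.
tiny_stack <- function(dim = c(6, 7, 4), voxel = c(1, 1, 5), seed = 11) {
  set.seed(seed)
  image_stack(array(runif(prod(dim), 0, 100), dim), voxel, channel = "test")
}

# A hand-built straight skeleton line of n voxels along x.
line_mask <- function(n = 11, pad = 2, voxel = 1) {
  d <- c(2 * pad + 1, n + 2 * pad, 2 * pad + 1)
  v <- array(FALSE, d)
  v[pad + 1, (pad + 1):(pad + n), pad + 1] <- TRUE
  image_stack(v, voxel)
}

# Long-format group data: list of numeric vectors -> data frame.
group_df <- function(...) {
  gs <- list(...)
  if (is.null(names(gs))) names(gs) <- letters[seq_along(gs)]
  data.frame(
    value = unlist(gs, use.names = FALSE),
    group = rep(names(gs), lengths(gs))
  )
}

# Independent Games-Howell implementation used as a dual-route oracle.
games_howell_oracle <- function(groups) {
  k <- length(groups)
  nm <- names(groups)
  out <- NULL
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      xi <- groups[[i]]
      xj <- groups[[j]]
      vi <- var(xi) / length(xi)
      vj <- var(xj) / length(xj)
      t <- (mean(xi) - mean(xj)) / sqrt(vi + vj)
      df <- (vi + vj)^2 / (vi^2 / (length(xi) - 1) + vj^2 / (length(xj) - 1))
      p <- ptukey(abs(t) * sqrt(2), k, df, lower.tail = FALSE)
      out <- rbind(out, data.frame(g1 = nm[i], g2 = nm[j], t = t, df = df, p = p))
    }
  }
  out
}
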