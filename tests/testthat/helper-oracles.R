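# Independent brute-force oracles, deliberately naive and separate from the
# package's own code paths.

# Voxel-visit count map: resample every streamline at `res` mm, map samples to
# voxels of the (possibly refined) grid, tally unique voxels per streamline.
brute_force_count_map <- function(streamlines, grid, factor = 1L,
                                  res = 0.01) {
  nd <- grid$dim * factor
  nvox <- prod(nd)
  vx <- grid$vox / factor
  orig <- grid$origin - grid$vox / 2 + vx / 2
  counts <- numeric(nvox)
  for (pts in streamlines) {
    samp <- pts
    if (nrow(pts) > 1) {
      acc <- list()
      for (i in seq_len(nrow(pts) - 1)) {
        a <- pts[i, ]; b <- pts[i + 1, ]
        L <- sqrt(sum((b - a)^2))
        n <- max(1L, ceiling(L / res))
        f <- seq(0, 1, length.out = n + 1)
        acc[[i]] <- cbind(a[1] + f * (b[1] - a[1]), a[2] + f * (b[2] - a[2]),
                          a[3] + f * (b[3] - a[3]))
      }
      samp <- do.call(rbind, acc)
    }
    v <- round(sweep(sweep(samp, 2, orig, "-"), 2, vx, "/"))
    ok <- v[, 1] >= 0 & v[, 1] < nd[1] & v[, 2] >= 0 & v[, 2] < nd[2] &
      v[, 3] >= 0 & v[, 3] < nd[3]
    v <- v[ok, , drop = FALSE]
    lin <- unique(v[, 1] + nd[1] * (v[, 2] + nd[2] * v[, 3]))
    counts[lin + 1] <- counts[lin + 1] + 1
  }
  array(counts, nd)
}

# Dice from raw index sets (independent of the package's mask arithmetic).
brute_force_dice <- function(idxA, idxB) {
  a <- nrow(idxA); b <- nrow(idxB)
  inter <- nrow(merge(as.data.frame(idxA), as.data.frame(idxB)))
  2 * inter / (a + b)
}

# Random wiggly streamline inside a grid (for oracle comparisons).
random_streamline <- function(grid, n_pts = 30, step = 0.8) {
  lo <- grid$origin + 2 * grid$vox
  hi <- grid$origin + (grid$dim - 3) * grid$vox
  p <- runif(3, lo + 2, hi - 2)
  d <- tractopt:::unit(rnorm(3))
  pts <- matrix(0, n_pts, 3)
  pts[1, ] <- p
  for (i in 2:n_pts) {
    d <- tractopt:::unit(d + 0.4 * rnorm(3))
    p2 <- p + step * d
    p2 <- pmin(pmax(p2, lo), hi)
    pts[i, ] <- p2
    p <- p2
  }
  pts
}
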