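#' Expand a single-slice ROI along its slice axis
#'
#' Replicates a single-slice ROI onto `n_up` and `n_down` additional slices
#' (clamped at the volume boundary), the standard thickening applied before
#' resampling waypoint ROIs to a coarser subject space: 2 up + 2 down gives a
#' 5-slice ROI, i.e. 1.25 mm thickness at 0.25 mm slice spacing.
#'
#' @param roi a single-slice [vox_mask()] (slice axis taken from the `"axis"`
#'   attribute, default 3).
#' @param n_up,n_down number of additional slices in each direction.
#' @param axis override for the expansion axis (1, 2 or 3).
#' @return A [vox_mask()] with attributes `"axis"` and `"thickness_mm"`.
#' @export
expand_roi <- function(roi, n_up = 2, n_down = 2, axis = NULL) {
  ax <- axis %||% attr(roi, "axis") %||% 3L
  idx <- mask_indices(roi)
  if (nrow(idx) == 0) stop("ROI is empty")
  slices <- unique(idx[, ax])
  if (length(slices) != 1L)
    stop("expand_roi requires a single-slice ROI along the expansion axis")
  if (n_up < 0 || n_down < 0) stop("n_up and n_down must be >= 0")
  target <- unique(pmin(pmax(slices + seq(-n_down, n_up), 1L),
                        roi$grid$dim[ax]))
  out <- do.call(rbind, lapply(target, function(s) {
    i <- idx
    i[, ax] <- s
    i
  }))
  m <- mask_from_indices(unique(out), roi$grid)
  attr(m, "axis") <- ax
  attr(m, "thickness_mm") <- length(target) * roi$grid$vox[ax]
  m
}

#' Warp a binary mask with a displacement field
#'
#' Nearest-neighbour pullback: the output voxel at `x` (on the target grid)
#' takes the mask value at `x + d(x)`. Points falling outside the mask grid
#' map to background. An empty result is allowed but reported.
#'
#' @param mask a [vox_mask()].
#' @param displacement array `c(target_grid$dim, 3)` of mm displacements
#'   defined over the target grid.
#' @param target_grid a [vox_grid()].
#' @return A [vox_mask()] on the target grid.
#' @export
warp_mask <- function(mask, displacement, target_grid) {
  d <- target_grid$dim
  if (!identical(as.integer(dim(displacement)[1:3]), d) ||
      dim(displacement)[4] != 3L)
    stop("displacement field does not match the target grid")
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  x <- grid_mm(target_grid, idx)
  src <- x + matrix(displacement, ncol = 3)
  sv <- grid_voxel(mask$grid, src)
  ok <- in_grid(mask$grid, sv)
  val <- logical(nrow(sv))
  if (any(ok)) val[ok] <- mask$data[sv[ok, , drop = FALSE]]
  out <- vox_mask(array(val, d), target_grid)
  if (sum(out$data) == 0)
    message("warp_mask: warped mask is empty")
  out
}

#' Crop a volume to an axis-aligned bounding-box mask
#'
#' @param volume a [vox_mask()], [orientation_field()] or plain array with a
#'   `grid` attribute-compatible list (`list(data=, grid=)`).
#' @param bbox a [vox_mask()] that is a filled axis-aligned box.
#' @return The same kind of object on the cropped grid; voxel values inside
#'   the box are preserved bit-exact.
#' @export
crop_to_bbox <- function(volume, bbox) {
  idx <- mask_indices(bbox)
  if (nrow(idx) == 0) stop("bounding box mask is empty")
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  if (nrow(idx) != prod(hi - lo + 1L))
    stop("bounding box mask is not a filled axis-aligned box")
  g <- bbox$grid
  newgrid <- vox_grid(hi - lo + 1L, g$vox, g$origin + (lo - 1) * g$vox)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  if (inherits(volume, "vox_mask")) {
    if (!same_grid(volume$grid, g)) stop("volume and bbox grids differ")
    return(vox_mask(volume$data[xs, ys, zs, drop = FALSE], newgrid))
  }
  if (inherits(volume, "orientation_field")) {
    if (!same_grid(volume$grid, g)) stop("volume and bbox grids differ")
    return(orientation_field(newgrid,
                             volume$dirs[, , xs, ys, zs, drop = FALSE],
                             volume$amps[, xs, ys, zs, drop = FALSE],
                             volume$nfix[xs, ys, zs, drop = FALSE]))
  }
  if (is.list(volume) && !is.null(volume$data)) {
    if (!same_grid(volume$grid, g)) stop("volume and bbox grids differ")
    return(list(data = volume$data[xs, ys, zs, drop = FALSE], grid = newgrid))
  }
  stop("unsupported volume type")
}

# Catmull-Rom cubic kernel.
cubic_w <- function(t) {
  at <- abs(t)
  ifelse(at < 1, 1.5 * at^3 - 2.5 * at^2 + 1,
         ifelse(at < 2, -0.5 * at^3 + 2.5 * at^2 - 4 * at + 2, 0))
}

# Separable cubic interpolation of a 3D array at mm points (edge-clamped).
cubic_interp3 <- function(arr, grid, pts) {
  d <- grid$dim
  g <- sweep(sweep(rbind(pts), 2, grid$origin, "-"), 2, grid$vox, "/") + 1
  g <- pmin(pmax(g, 1), rep(d, each = nrow(g)))
  f0 <- floor(g)
  fr <- g - f0
  out <- numeric(nrow(g))
  for (ox in -1:2) for (oy in -1:2) for (oz in -1:2) {
    w <- cubic_w(ox - fr[, 1]) * cubic_w(oy - fr[, 2]) * cubic_w(oz - fr[, 3])
    if (all(w == 0)) next
    ix <- pmin(pmax(f0[, 1] + ox, 1), d[1])
    iy <- pmin(pmax(f0[, 2] + oy, 1), d[2])
    iz <- pmin(pmax(f0[, 3] + oz, 1), d[3])
    out <- out + w * arr[cbind(ix, iy, iz)]
  }
  out
}

#' Resample an orientation field to a new voxel size
#'
#' Amplitudes are resampled with (Catmull-Rom) cubic interpolation and clipped
#' at zero; directions are assigned from the nearest source voxel (fixel
#' directions do not interpolate naturally), so unit norms are preserved
#' exactly.
#'
#' @param field an [orientation_field()].
#' @param target_vox target voxel size in mm (scalar or length-3).
#' @return An [orientation_field()] whose grid covers the same mm extent.
#' @export
resample_field <- function(field, target_vox) {
  target_vox <- rep_len(as.numeric(target_vox), 3)
  if (any(target_vox <= 0)) stop("target voxel size must be > 0")
  g <- field$grid
  extent <- g$dim * g$vox
  nd <- as.integer(ceiling(extent / target_vox - 1e-9))
  newgrid <- vox_grid(nd, target_vox,
                      g$origin - g$vox / 2 + target_vox / 2)
  idx <- as.matrix(expand.grid(seq_len(nd[1]), seq_len(nd[2]),
                               seq_len(nd[3])))
  pts <- grid_mm(newgrid, idx)
  sv <- grid_voxel(g, pts)
  sv[, 1] <- pmin(pmax(sv[, 1], 1L), g$dim[1])
  sv[, 2] <- pmin(pmax(sv[, 2], 1L), g$dim[2])
  sv[, 3] <- pmin(pmax(sv[, 3], 1L), g$dim[3])
  sl <- sv[, 1] + g$dim[1] * ((sv[, 2] - 1) + g$dim[2] * (sv[, 3] - 1))
  nfix <- array(field$nfix[sl], nd)
  dirm <- matrix(field$dirs, nrow = 9)
  dirs <- array(dirm[, sl], c(3, 3, nd))
  amps <- array(0, c(3, nd))
  for (f in 1:3) {
    a <- array(field$amps[f, , , ], g$dim)
    if (all(a == 0)) next
    av <- pmax(0, cubic_interp3(a, g, pts))
    # amplitude only where the nearest source voxel carries this fixel slot
    av[nfix[cbind(idx)] < f] <- 0
    amps[f, , , ] <- array(av, nd)
  }
  nfix2 <- apply(amps > 0, 2:4, sum)
  orientation_field(newgrid, dirs, amps, array(as.integer(nfix2), nd))
}
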