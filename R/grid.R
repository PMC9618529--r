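#' @useDynLib tractopt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Voxel grid geometry
#'
#' A minimal axis-aligned grid: integer dimensions, voxel edge lengths in mm,
#' and the mm coordinate of the centre of the first voxel. Voxel indices are
#' 1-based in R; the centre of voxel `(i,j,k)` is `origin + (c(i,j,k) - 1) * vox`.
#'
#' @param dim integer length-3 vector of voxel counts.
#' @param vox numeric length-3 voxel size in mm (a scalar is recycled).
#' @param origin mm coordinate of the first voxel centre.
#' @return An object of class `"vox_grid"`.
#' @export
vox_grid <- function(dim, vox = 1, origin = c(0, 0, 0)) {
  dim <- as.integer(rep_len(dim, 3L))
  vox <- as.numeric(rep_len(vox, 3L))
  origin <- as.numeric(rep_len(origin, 3L))
  if (any(dim < 1L)) stop("grid dimensions must be >= 1")
  if (any(vox <= 0)) stop("voxel size must be > 0")
  structure(list(dim = dim, vox = vox, origin = origin), class = "vox_grid")
}

#' @export
print.vox_grid <- function(x, ...) {
  cat(sprintf("<vox_grid> %s voxels @ %s mm, origin (%s) mm\n",
              paste(x$dim, collapse = "x"),
              paste(signif(x$vox, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$dim, b$dim) && all(abs(a$vox - b$vox) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Convert voxel indices to mm coordinates
#'
#' @param grid a [vox_grid()].
#' @param idx integer matrix (n x 3) of 1-based voxel indices.
#' @return n x 3 matrix of voxel-centre coordinates in mm.
#' @export
grid_mm <- function(grid, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx - 1, 2, grid$vox, "*"), 2, grid$origin, "+")
}

#' Convert mm coordinates to nearest voxel indices
#'
#' @param grid a [vox_grid()].
#' @param pts numeric matrix (n x 3) of mm coordinates.
#' @return n x 3 integer matrix of 1-based voxel indices (possibly out of range).
#' @export
grid_voxel <- function(grid, pts) {
  pts <- rbind(pts)
  v <- sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$vox, "/")
  matrix(as.integer(round(v)), ncol = 3) + 1L
}

in_grid <- function(grid, idx) {
  idx <- rbind(idx)
  idx[, 1] >= 1L & idx[, 1] <= grid$dim[1] &
    idx[, 2] >= 1L & idx[, 2] <= grid$dim[2] &
    idx[, 3] >= 1L & idx[, 3] <= grid$dim[3]
}

#' Binary voxel mask
#'
#' @param data logical (or coercible) array matching `grid$dim`.
#' @param grid a [vox_grid()].
#' @return An object of class `"vox_mask"`.
#' @export
vox_mask <- function(data, grid) {
  data <- array(as.logical(data), dim = grid$dim)
  structure(list(data = data, grid = grid), class = "vox_mask")
}

#' @export
print.vox_mask <- function(x, ...) {
  cat(sprintf("<vox_mask> %d of %d voxels set; ", sum(x$data),
              prod(x$grid$dim)))
  print(x$grid)
  invisible(x)
}

#' Mask from voxel index matrix
#' @param idx n x 3 matrix of 1-based voxel indices.
#' @param grid a [vox_grid()].
#' @return A [vox_mask()].
#' @export
mask_from_indices <- function(idx, grid) {
  idx <- rbind(idx)
  if (nrow(idx) && any(!in_grid(grid, idx)))
    stop("mask indices outside grid")
  m <- array(FALSE, grid$dim)
  if (nrow(idx)) m[idx] <- TRUE
  vox_mask(m, grid)
}

mask_indices <- function(mask) {
  which(mask$data, arr.ind = TRUE)
}

mask_count <- function(mask) sum(mask$data)

#' Discrete fixel orientation field
#'
#' Stores up to three fiber populations ("fixels") per voxel, each a unit
#' direction plus a non-negative amplitude (the tracking substrate; the
#' amplitude plays the role of the orientation-distribution peak height that
#' the tracking cutoff of 0.05 is compared against).
#'
#' @param grid a [vox_grid()].
#' @param dirs numeric array `c(3, 3, dim)`: component, fixel slot, voxel.
#' @param amps numeric array `c(3, dim)`: fixel slot, voxel.
#' @param nfix integer array `dim`: number of occupied fixel slots (0..3).
#' @return An object of class `"orientation_field"`.
#' @export
orientation_field <- function(grid, dirs, amps, nfix) {
  stopifnot(identical(dim(nfix), grid$dim) ||
              identical(as.integer(dim(nfix)), grid$dim))
  f <- structure(list(grid = grid,
                      dirs = array(as.numeric(dirs), c(3L, 3L, grid$dim)),
                      amps = array(as.numeric(amps), c(3L, grid$dim)),
                      nfix = array(as.integer(nfix), grid$dim)),
                 class = "orientation_field")
  validate_field(f)
  f
}

empty_field <- function(grid) {
  orientation_field(grid,
                    dirs = array(0, c(3, 3, grid$dim)),
                    amps = array(0, c(3, grid$dim)),
                    nfix = array(0L, grid$dim))
}

validate_field <- function(field, tol = 1e-6) {
  if (any(field$nfix < 0L) || any(field$nfix > 3L))
    stop("fixel counts must be in 0..3")
  if (any(field$amps < 0)) stop("fixel amplitudes must be >= 0")
  # unit-norm check on occupied fixel slots only
  nrm <- sqrt(colSums(matrix(field$dirs, nrow = 3)^2))
  nf <- as.vector(field$nfix)
  slot <- rep(1:3, times = length(nf))
  occupied <- slot <= rep(nf, each = 3)
  if (any(occupied) && any(abs(nrm[occupied] - 1) >= tol))
    stop("occupied fixel directions must be unit-norm")
  invisible(field)
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field> %d voxels with fixels (max %d/voxel); ",
              sum(x$nfix > 0L), max(x$nfix)))
  print(x$grid)
  invisible(x)
}

## ---- NIfTI I/O -------------------------------------------------------------

nifti_header_for <- function(grid, ndim4 = NULL) {
  h <- RNifti::niftiHeader(list(
    dim = c(if (is.null(ndim4)) 3L else 4L, grid$dim, ndim4 %||% 1L,
            1L, 1L, 1L),
    pixdim = c(1, grid$vox, 1, 0, 0, 0)))
  h$qform_code <- 2
  h$qoffset_x <- grid$origin[1]
  h$qoffset_y <- grid$origin[2]
  h$qoffset_z <- grid$origin[3]
  h
}

write_volume_nifti <- function(arr, grid, path) {
  ndim4 <- if (length(dim(arr)) == 4L) dim(arr)[4] else NULL
  img <- RNifti::asNifti(arr, reference = nifti_header_for(grid, ndim4))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  vox <- RNifti::pixdim(img)[1:3]
  grid <- vox_grid(dim(img)[1:3], vox, xf[1:3, 4])
  list(data = as.array(img), grid = grid)
}

#' Write a binary mask as uint8 NIfTI
#' @param mask a [vox_mask()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @export
write_mask_nifti <- function(mask, path) {
  arr <- array(as.integer(mask$data), mask$grid$dim)
  storage.mode(arr) <- "integer"
  write_volume_nifti(arr, mask$grid, path)
}

#' Read a binary mask from NIfTI
#' @param path file path.
#' @return A [vox_mask()].
#' @export
read_mask_nifti <- function(path) {
  v <- read_volume_nifti(path)
  vox_mask(v$data != 0, v$grid)
}

#' Write an orientation field as paired NIfTI volumes
#'
#' Directions are stored as a 4D float volume with 9 components (3 per fixel
#' slot), amplitudes as a 4D float volume with 3 components.
#'
#' @param field an [orientation_field()].
#' @param prefix path prefix; writes `<prefix>_dirs.nii.gz` and
#'   `<prefix>_amps.nii.gz`.
#' @return The two file paths, invisibly.
#' @export
write_field_nifti <- function(field, prefix) {
  d <- field$grid$dim
  dirs4 <- aperm(array(field$dirs, c(9, d)), c(2, 3, 4, 1))
  amps4 <- aperm(array(field$amps, c(3, d)), c(2, 3, 4, 1))
  p1 <- paste0(prefix, "_dirs.nii.gz")
  p2 <- paste0(prefix, "_amps.nii.gz")
  write_volume_nifti(dirs4, field$grid, p1)
  write_volume_nifti(amps4, field$grid, p2)
  invisible(c(p1, p2))
}

#' Read an orientation field written by [write_field_nifti()]
#' @param prefix path prefix used when writing.
#' @return An [orientation_field()].
#' @export
read_field_nifti <- function(prefix) {
  d1 <- read_volume_nifti(paste0(prefix, "_dirs.nii.gz"))
  a1 <- read_volume_nifti(paste0(prefix, "_amps.nii.gz"))
  grid <- d1$grid
  dirs <- array(aperm(d1$data, c(4, 1, 2, 3)), c(3, 3, grid$dim))
  amps <- array(aperm(a1$data, c(4, 1, 2, 3)), c(3, grid$dim))
  nfix <- apply(amps > 0, 2:4, sum)
  # renormalize against float32 round-off so unit-norm invariant holds
  nrm <- sqrt(colSums(matrix(dirs, nrow = 3)^2))
  nrm[nrm == 0] <- 1
  dirs <- array(sweep(matrix(dirs, nrow = 3), 2, nrm, "/"), c(3, 3, grid$dim))
  orientation_field(grid, dirs, amps, array(as.integer(nfix), grid$dim))
}
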