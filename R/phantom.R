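#' Specify a synthetic fiber bundle
#'
#' A bundle is a tube of constant radius around a centerline, which is either
#' an explicit polyline or a circular arc (centre, radius, plane, angular
#' span). The tube is rasterized into an orientation field with one fixel per
#' bundle per voxel, direction equal to the local centerline tangent.
#'
#' @param name bundle label.
#' @param centerline n x 3 matrix of mm points (>= 2 distinct points), or
#'   `NULL` when an arc is given.
#' @param arc optional list with elements `center` (mm), `radius` (mm), `u`,
#'   `v` (orthonormal in-plane axes) and `theta` (length-2 angular span in
#'   degrees); the centerline is `center + radius*(cos(t) u + sin(t) v)`.
#' @param tube_radius tube radius in mm (> 0).
#' @param amplitude fixel amplitude in (0, 1].
#' @return An object of class `"bundle_spec"`.
#' @export
bundle_spec <- function(name, centerline = NULL, arc = NULL, tube_radius = 2,
                        amplitude = 0.6) {
  if (tube_radius <= 0) stop("tube_radius must be > 0")
  if (amplitude <= 0 || amplitude > 1) stop("amplitude must be in (0, 1]")
  if (is.null(centerline) && is.null(arc))
    stop("either centerline or arc must be given")
  if (!is.null(centerline)) {
    centerline <- rbind(centerline)
    if (nrow(unique(centerline)) < 2)
      stop("centerline needs at least 2 distinct points")
  }
  structure(list(name = name, centerline = centerline, arc = arc,
                 tube_radius = tube_radius, amplitude = amplitude),
            class = "bundle_spec")
}

# Densely sampled centerline polyline (mm) at roughly `spacing` arc length.
bundle_polyline <- function(bundle, spacing = 0.1) {
  if (!is.null(bundle$arc)) {
    a <- bundle$arc
    th <- a$theta * pi / 180
    arclen <- abs(diff(th)) * a$radius
    n <- max(2L, ceiling(arclen / spacing) + 1L)
    t <- seq(th[1], th[2], length.out = n)
    p <- matrix(a$center, n, 3, byrow = TRUE) +
      a$radius * (outer(cos(t), a$u) + outer(sin(t), a$v))
    return(p)
  }
  cl <- bundle$centerline
  seg <- diff(cl)
  lens <- sqrt(rowSums(seg^2))
  out <- list(cl[1, , drop = FALSE])
  for (i in seq_len(nrow(seg))) {
    n <- max(1L, ceiling(lens[i] / spacing))
    f <- seq_len(n) / n
    out[[i + 1]] <- cl[rep(i, n), , drop = FALSE] + outer(f, seg[i, ])
  }
  do.call(rbind, out)
}

# Unit tangents of a polyline (forward differences, last repeated).
polyline_tangents <- function(p) {
  d <- diff(p)
  d <- rbind(d, d[nrow(d), , drop = FALSE])
  n <- sqrt(rowSums(d^2))
  n[n == 0] <- 1
  d / n
}

check_inside <- function(poly, grid, margin, name) {
  lo <- grid$origin - grid$vox / 2
  hi <- grid$origin + (grid$dim - 0.5) * grid$vox
  pad <- margin * grid$vox
  if (any(t(poly) < lo + pad) || any(t(poly) > hi - pad))
    stop(sprintf("bundle '%s': centerline exits the grid (margin %g voxels)",
                 name, margin))
}

#' Rasterize bundles into an orientation field
#'
#' Every voxel whose centre lies within `tube_radius` of a bundle centerline
#' receives one fixel for that bundle: direction = the local centerline
#' tangent, amplitude = the bundle amplitude. Where more than three bundles
#' overlap, the three largest-amplitude fixels are kept.
#'
#' @param bundles list of [bundle_spec()] objects.
#' @param grid a [vox_grid()].
#' @return An [orientation_field()].
#' @export
make_bundle_field <- function(bundles, grid) {
  field <- empty_field(grid)
  for (b in bundles) {
    poly <- bundle_polyline(b)
    check_inside(poly, grid, 2, b$name)
    tang <- polyline_tangents(poly)
    r <- cpp_polyline_rast(poly, grid$dim, grid$vox, grid$origin,
                           b$tube_radius)
    for (i in seq_along(r$index)) {
      l <- r$index[i]
      d <- tang[r$nearest[i], ]
      nf <- field$nfix[l]
      if (nf < 3L) {
        slot <- nf + 1L
        field$nfix[l] <- slot
      } else {
        # cap at 3 fixels: replace the weakest if this bundle is stronger
        amps <- field$amps[(3 * (l - 1) + 1):(3 * l)]
        slot <- which.min(amps)
        if (amps[slot] >= b$amplitude) next
      }
      field$dirs[(9 * (l - 1) + 3 * (slot - 1) + 1):(9 * (l - 1) + 3 * slot)] <-
        unit(d)
      field$amps[3 * (l - 1) + slot] <- b$amplitude
    }
  }
  field
}

#' Ground-truth tube mask for a bundle
#'
#' The set of voxels whose centres lie within `tube_radius` of the bundle
#' centerline; the phantom stand-in for a manual whole-course tract
#' delineation.
#'
#' @param bundle a [bundle_spec()].
#' @param grid a [vox_grid()].
#' @return A [vox_mask()].
#' @export
ground_truth_mask <- function(bundle, grid) {
  poly <- bundle_polyline(bundle)
  check_inside(poly, grid, 2, bundle$name)
  r <- cpp_polyline_rast(poly, grid$dim, grid$vox, grid$origin,
                         bundle$tube_radius)
  if (length(r$index) == 0)
    stop(sprintf("bundle '%s': ground-truth mask is empty", bundle$name))
  m <- array(FALSE, grid$dim)
  m[r$index] <- TRUE
  vox_mask(m, grid)
}

#' Single-slice waypoint ROIs along a bundle
#'
#' Places `n_rois` single-slice disc ROIs centred on the centerline at evenly
#' spaced arc-length fractions (0.1 and 0.9 for the first and last, the rest
#' evenly in between; endpoints only when `n_rois = 2`). The slice axis of
#' each ROI is the coordinate axis most parallel to the local tangent, stored
#' in the `"axis"` attribute for later expansion.
#'
#' @param bundle a [bundle_spec()].
#' @param grid a [vox_grid()].
#' @param n_rois number of ROIs (>= 2; default 3).
#' @param roi_radius in-plane disc radius in mm (default: the tube radius).
#' @return List of single-slice [vox_mask()] objects with attributes `"axis"`
#'   (1, 2 or 3) and `"slice"` (voxel index along that axis).
#' @export
make_waypoint_rois <- function(bundle, grid, n_rois = 3,
                               roi_radius = bundle$tube_radius) {
  if (n_rois < 2) stop("n_rois must be >= 2")
  poly <- bundle_polyline(bundle)
  tang <- polyline_tangents(poly)
  seglen <- c(0, cumsum(sqrt(rowSums(diff(poly)^2))))
  total <- seglen[length(seglen)]
  fr <- if (n_rois == 2) c(0.1, 0.9) else
    seq(0.1, 0.9, length.out = n_rois)
  lapply(fr, function(f) {
    i <- which.min(abs(seglen - f * total))
    p <- poly[i, ]
    ax <- which.max(abs(tang[i, ]))
    sl <- grid_voxel(grid, rbind(p))[1, ax]
    sl <- min(max(sl, 1L), grid$dim[ax])
    idx <- as.matrix(expand.grid(seq_len(grid$dim[1]), seq_len(grid$dim[2]),
                                 seq_len(grid$dim[3])))
    idx <- idx[idx[, ax] == sl, , drop = FALSE]
    ctr <- grid_mm(grid, idx)
    inplane <- setdiff(1:3, ax)
    d2 <- rowSums((ctr[, inplane, drop = FALSE] -
                     rep(p[inplane], each = nrow(ctr)))^2)
    keep <- idx[d2 <= roi_radius^2, , drop = FALSE]
    if (nrow(keep) == 0)
      stop(sprintf("bundle '%s': waypoint ROI empty after rasterization",
                   bundle$name))
    m <- mask_from_indices(keep, grid)
    attr(m, "axis") <- ax
    attr(m, "slice") <- sl
    m
  })
}

#' Default subthalamic-like phantom suite
#'
#' Four bundles of graded curvature in a 40 mm cube at 1 mm voxels: a straight
#' bundle (mammillothalamic-tract analogue, "MTT"), a gently curved 90-degree
#' arc of radius 10 mm (cerebello-thalamic analogue, "CTT"), a strongly curved
#' 160-degree arc of radius 4 mm (ansa-lenticularis analogue, "AL"), and a
#' straight bundle crossing the AL arc at 90 degrees (fasciculus-lenticularis /
#' internal-capsule analogue, "FL"). The curvature ordering is what drives the
#' algorithm/parameter dissociation the optimization is meant to detect.
#'
#' @param tube_radius tube radius in mm for all bundles.
#' @param amplitude fixel amplitude for all bundles.
#' @return List with elements `grid`, `bundles` (named list of
#'   [bundle_spec()]), `truth` (named list of masks), `rois` (named list of
#'   ROI lists) and `field` (the template [orientation_field()]).
#' @export
default_phantom <- function(tube_radius = 2, amplitude = 0.6) {
  grid <- vox_grid(c(40L, 40L, 40L), 1)
  bundles <- list(
    MTT = bundle_spec("MTT", centerline = rbind(c(8, 8, 5), c(8, 8, 34)),
                      tube_radius = tube_radius, amplitude = amplitude),
    CTT = bundle_spec("CTT", arc = list(center = c(22, 30, 8), radius = 10,
                                        u = c(1, 0, 0), v = c(0, 0, 1),
                                        theta = c(0, 90)),
                      tube_radius = tube_radius, amplitude = amplitude),
    AL = bundle_spec("AL", arc = list(center = c(20, 20, 28), radius = 4,
                                      u = c(1, 0, 0), v = c(0, 1, 0),
                                      theta = c(-80, 80)),
                     tube_radius = tube_radius, amplitude = amplitude),
    FL = bundle_spec("FL", centerline = rbind(c(5, 20, 28), c(35, 20, 28)),
                     tube_radius = tube_radius, amplitude = amplitude))
  truth <- lapply(bundles, ground_truth_mask, grid = grid)
  rois <- lapply(bundles, make_waypoint_rois, grid = grid)
  list(grid = grid, bundles = bundles, truth = truth, rois = rois,
       ic_tract = "FL", field = make_bundle_field(bundles, grid))
}

#' Cohort specification
#'
#' @param n_subjects number of subjects (>= 1).
#' @param warp_amplitude maximum displacement of the random nonlinear warp, mm.
#' @param warp_smoothness Gaussian smoothing kernel sd of the warp, mm.
#' @param amplitude_noise_sd sd of iid fixel-amplitude noise (truncated at 0).
#' @param direction_noise_sd sd (degrees) of the per-fixel random direction
#'   jitter applied with each noise replicate; models orientation-estimation
#'   uncertainty. Set to 0 for a noise-free cohort.
#' @param n_retest number of subjects with a second (retest) replicate that
#'   differs only in the noise draw.
#' @param rng_seed integer seed; cohorts are pure functions of
#'   (template, spec).
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 20, warp_amplitude = 2,
                        warp_smoothness = 8, amplitude_noise_sd = 0.05,
                        direction_noise_sd = 5, n_retest = 5, rng_seed = 1) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (n_retest > n_subjects) stop("n_retest must be <= n_subjects")
  if (warp_amplitude < 0 || warp_smoothness <= 0)
    stop("warp parameters must be non-negative (smoothness > 0)")
  if (amplitude_noise_sd < 0 || direction_noise_sd < 0)
    stop("noise sds must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 warp_amplitude = warp_amplitude,
                 warp_smoothness = warp_smoothness,
                 amplitude_noise_sd = amplitude_noise_sd,
                 direction_noise_sd = direction_noise_sd,
                 n_retest = as.integer(n_retest),
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

# Separable Gaussian smoothing of a 3D array, kernel sd in voxels per axis.
gauss_smooth3d <- function(arr, sd_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sd_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    n <- d[ax]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmin(pmax(i + seq(-r, r), 1L), n) # edge replication
      for (t in seq_along(j)) K[i, j[t]] <- K[i, j[t]] + k[t]
    }
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    m <- matrix(a, nrow = d[ax])
    a <- array(K %*% m, dim = d[perm])
    arr <- aperm(a, order(perm))
  }
  arr
}

# Random displacement field: small affine jitter (<= 2 deg rotation, <= 2%
# scale) plus a Gaussian-smoothed random field rescaled so its maximum
# magnitude equals `amplitude` mm. Returns array c(dim, 3) of mm displacements
# on the template grid.
random_displacement <- function(grid, amplitude, smoothness) {
  d <- grid$dim
  u <- array(0, c(d, 3))
  if (amplitude <= 0) return(u)
  # affine jitter about the grid centre
  ctr <- grid$origin + (d - 1) / 2 * grid$vox
  ang <- stats::runif(1, 0, 2) * pi / 180
  z <- stats::runif(1, -1, 1); ph <- stats::runif(1, 0, 2 * pi)
  axis <- c(sqrt(1 - z^2) * cos(ph), sqrt(1 - z^2) * sin(ph), z)
  sc <- 1 + stats::runif(1, -0.02, 0.02)
  A <- sc * rotation_about(axis, ang)
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  x <- grid_mm(grid, idx)
  xa <- sweep(sweep(x, 2, ctr, "-") %*% t(A), 2, ctr, "+")
  for (k in 1:3) u[, , , k] <- array(xa[, k] - x[, k], d)
  # nonlinear part
  nl <- array(stats::rnorm(prod(d) * 3), c(d, 3))
  sdv <- smoothness / grid$vox
  for (k in 1:3) nl[, , , k] <- gauss_smooth3d(nl[, , , k], sdv)
  mag <- sqrt(nl[, , , 1]^2 + nl[, , , 2]^2 + nl[, , , 3]^2)
  mx <- max(mag)
  if (mx > 0) nl <- nl * (amplitude / 2 / mx)
  # affine jitter is also scaled down if it alone exceeds the budget
  amag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
  if (max(amag) > amplitude / 2) u <- u * (amplitude / 2 / max(amag))
  u + nl
}

# Trilinear interpolation of a displacement field (array c(dim,3), template
# grid) at mm points; coordinates clamped to the grid.
interp_displacement <- function(u, grid, pts) {
  d <- grid$dim
  pts <- rbind(pts)
  g <- sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$vox, "/") + 1
  g <- pmin(pmax(g, 1), rep(d, each = nrow(g)))
  f0 <- pmin(floor(g), rep(d - 1L, each = nrow(g)))
  fr <- g - f0
  out <- matrix(0, nrow(pts), 3)
  um <- matrix(u, ncol = 3)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (cx * fr[, 1] + (1 - cx) * (1 - fr[, 1])) *
      (cy * fr[, 2] + (1 - cy) * (1 - fr[, 2])) *
      (cz * fr[, 3] + (1 - cz) * (1 - fr[, 3]))
    ii <- (f0[, 1] + cx) + d[1] * ((f0[, 2] + cy - 1) +
                                     d[2] * (f0[, 3] + cz - 1))
    out <- out + w * um[ii, , drop = FALSE]
  }
  out
}

# Approximate inverse displacement by fixed-point iteration:
# v(y) solves y + v(y) = W^{-1}(y) where W(x) = x + u(x).
invert_displacement <- function(u, grid, iters = 25) {
  d <- grid$dim
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  y <- grid_mm(grid, idx)
  v <- -matrix(u, ncol = 3)
  for (i in seq_len(iters)) {
    v <- -interp_displacement(u, grid, y + v)
  }
  array(v, c(d, 3))
}

# Maximum forward-inverse round-trip error in mm over the template grid.
roundtrip_error <- function(u, v, grid) {
  d <- grid$dim
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  x <- grid_mm(grid, idx)
  fwd <- x + matrix(u, ncol = 3)
  back <- fwd + interp_displacement(v, grid, fwd)
  max(sqrt(rowSums((back - x)^2)))
}

# Pull the template field through the inverse warp onto the (identical)
# subject grid, reorienting directions by the local warp Jacobian.
warp_field_to_subject <- function(template, u, v) {
  grid <- template$grid
  d <- grid$dim
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  y <- grid_mm(grid, idx)
  src_mm <- y + matrix(v, ncol = 3)
  src_vox <- grid_voxel(grid, src_mm)
  src_vox[, 1] <- pmin(pmax(src_vox[, 1], 1L), d[1])
  src_vox[, 2] <- pmin(pmax(src_vox[, 2], 1L), d[2])
  src_vox[, 3] <- pmin(pmax(src_vox[, 3], 1L), d[3])
  src_lin <- src_vox[, 1] + d[1] * ((src_vox[, 2] - 1) +
                                      d[2] * (src_vox[, 3] - 1))
  out <- empty_field(grid)
  out$nfix <- array(template$nfix[src_lin], d)
  ampm <- matrix(template$amps, nrow = 3)
  out$amps <- array(ampm[, src_lin], c(3, d))
  # Jacobian of the forward map at the source voxel (central differences)
  J <- jacobian_of(u, grid)
  dirm <- matrix(template$dirs, nrow = 9)
  occ <- which(out$nfix > 0L)
  odir <- matrix(0, 9, prod(d))
  for (l in occ) {
    sl <- src_lin[l]
    Jl <- matrix(J[, sl], 3, 3)
    nf <- template$nfix[sl]
    D <- matrix(dirm[, sl], 3, 3)
    for (f in seq_len(nf)) {
      dd <- Jl %*% D[, f]
      odir[(3 * (f - 1) + 1):(3 * f), l] <- dd / vnorm(dd)
    }
  }
  out$dirs <- array(odir, c(3, 3, d))
  out
}

# 3x3 Jacobians of x -> x + u(x) at every voxel, returned as 9 x nvox matrix
# (column-major 3x3 per voxel).
jacobian_of <- function(u, grid) {
  d <- grid$dim
  nvox <- prod(d)
  J <- matrix(0, 9, nvox)
  um <- array(u, c(d, 3))
  for (k in 1:3) {     # displacement component
    for (ax in 1:3) {  # derivative axis
      g <- grad_axis(um[, , , k], ax, grid$vox[ax])
      J[k + 3 * (ax - 1), ] <- as.vector(g) + (k == ax)
    }
  }
  J
}

grad_axis <- function(a, ax, h) {
  d <- dim(a)
  n <- d[ax]
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = n)
  g <- m
  if (n >= 3) {
    g[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * h)
    g[1, ] <- (m[2, ] - m[1, ]) / h
    g[n, ] <- (m[n, ] - m[n - 1, ]) / h
  } else {
    g[] <- 0
  }
  aperm(array(g, d[perm]), order(perm))
}

# Apply one replicate's noise draw to a warped subject field.
apply_field_noise <- function(field, amplitude_noise_sd, direction_noise_sd) {
  out <- field
  occ_vox <- which(field$nfix > 0L)
  if (length(occ_vox) == 0) return(out)
  ampm <- matrix(out$amps, nrow = 3)
  dirm <- array(out$dirs, c(3, 3, prod(field$grid$dim)))
  for (l in occ_vox) {
    nf <- field$nfix[l]
    for (f in seq_len(nf)) {
      if (amplitude_noise_sd > 0)
        ampm[f, l] <- max(0, ampm[f, l] + stats::rnorm(1, 0, amplitude_noise_sd))
      if (direction_noise_sd > 0) {
        R <- random_rotation(direction_noise_sd)
        dirm[, f, l] <- R %*% dirm[, f, l]
      }
    }
  }
  out$amps <- array(ampm, c(3, field$grid$dim))
  out$dirs <- array(dirm, c(3, 3, field$grid$dim))
  out
}

#' Generate a synthetic multi-subject cohort
#'
#' Each subject is the template orientation field pulled through a smooth
#' random warp (small affine jitter plus a Gaussian-smoothed random
#' displacement field), with directions reoriented by the local warp Jacobian
#' and per-fixel amplitude and direction noise. The first `n_retest` subjects
#' receive a second replicate differing only in the noise draw. Fully
#' reproducible from `spec$rng_seed`.
#'
#' @param template an [orientation_field()].
#' @param spec a [cohort_spec()].
#' @return An object of class `"phantom_cohort"`: list with `subjects` (each
#'   with `subject_id`, `field`, optional `field_retest`, `warp_from_template`
#'   (forward displacement `u`, template to subject, mm, on the template grid),
#'   `warp_to_template` (approximate inverse `v`), `replicate_tag`), plus the
#'   `spec` and the template `grid`.
#' @export
make_cohort <- function(template, spec) {
  grid <- template$grid
  tol <- 0.25 * min(grid$vox)
  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    set.seed(derive_seed(spec$rng_seed, "warp", s))
    amp <- spec$warp_amplitude
    ok <- FALSE
    for (try in 1:5) {
      u <- random_displacement(grid, amp, spec$warp_smoothness)
      v <- invert_displacement(u, grid)
      if (amp == 0 || roundtrip_error(u, v, grid) < tol) { ok <- TRUE; break }
      amp <- amp * 0.7
      warning(sprintf("subject %d: warp round-trip above tolerance, %s",
                      s, "regenerating with reduced amplitude"))
    }
    if (!ok) stop(sprintf("subject %d: warp inversion failed after 5 tries", s))
    clean <- if (spec$warp_amplitude == 0) template else
      warp_field_to_subject(template, u, v)
    set.seed(derive_seed(spec$rng_seed, "noise", s, 1L))
    fld <- apply_field_noise(clean, spec$amplitude_noise_sd,
                             spec$direction_noise_sd)
    subj <- list(subject_id = sprintf("sub-%03d", s), field = fld,
                 warp_from_template = u, warp_to_template = v,
                 replicate_tag = if (s <= spec$n_retest) "test" else "none")
    if (s <= spec$n_retest) {
      set.seed(derive_seed(spec$rng_seed, "noise", s, 2L))
      subj$field_retest <- apply_field_noise(clean, spec$amplitude_noise_sd,
                                             spec$direction_noise_sd)
    }
    subjects[[s]] <- subj
  }
  structure(list(subjects = subjects, spec = spec, grid = grid),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects (%d with retest), warp %g mm / %g mm, noise sd %g / %g deg, seed %d\n",
              x$spec$n_subjects, x$spec$n_retest, x$spec$warp_amplitude,
              x$spec$warp_smoothness, x$spec$amplitude_noise_sd,
              x$spec$direction_noise_sd, x$spec$rng_seed))
  invisible(x)
}

#' Write a cohort to disk as NIfTI volumes plus a YAML manifest
#'
#' @param cohort a [make_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort$subjects, function(s) {
    prefix <- file.path(dir, s$subject_id)
    write_field_nifti(s$field, prefix)
    files <- list(field = paste0(basename(prefix), c("_dirs.nii.gz",
                                                     "_amps.nii.gz")))
    if (!is.null(s$field_retest)) {
      write_field_nifti(s$field_retest, paste0(prefix, "_retest"))
      files$retest <- paste0(basename(prefix),
                             c("_retest_dirs.nii.gz", "_retest_amps.nii.gz"))
    }
    write_volume_nifti(array(s$warp_from_template,
                             c(cohort$grid$dim, 3)), cohort$grid,
                       paste0(prefix, "_warp_fwd.nii.gz"))
    write_volume_nifti(array(s$warp_to_template,
                             c(cohort$grid$dim, 3)), cohort$grid,
                       paste0(prefix, "_warp_inv.nii.gz"))
    c(list(subject_id = s$subject_id, replicate_tag = s$replicate_tag), files)
  })
  manifest <- list(n_subjects = cohort$spec$n_subjects,
                   n_retest = cohort$spec$n_retest,
                   rng_seed = cohort$spec$rng_seed,
                   warp_amplitude = cohort$spec$warp_amplitude,
                   warp_smoothness = cohort$spec$warp_smoothness,
                   amplitude_noise_sd = cohort$spec$amplitude_noise_sd,
                   direction_noise_sd = cohort$spec$direction_noise_sd,
                   subjects = entries)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
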