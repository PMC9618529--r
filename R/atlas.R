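#' Binarize a track-density map
#'
#' A voxel is retained iff its streamline count is at least a fraction
#' (default 15%) of the map's maximum voxel density. The maximum voxel always
#' survives, so the result is nonempty by construction, and the mask is
#' invariant to rescaling all counts by a positive constant.
#'
#' @param tdi a count-contrast `"tdi_map"`.
#' @param fraction density threshold as a fraction of the map maximum.
#' @param mode `"max"` (fraction of the maximum voxel density, the default
#'   reading) or `"total"` (fraction of the total streamline count, exposed
#'   because the phrasing "15% of its streamline density" admits both).
#' @return A [vox_mask()].
#' @export
binarize_tdi <- function(tdi, fraction = 0.15, mode = c("max", "total")) {
  mode <- match.arg(mode)
  v <- tdi$values
  mx <- max(v)
  if (mx <= 0) stop("binarize_tdi: all-zero density map")
  thr <- if (mode == "max") fraction * mx else fraction * sum(v)
  vox_mask(v >= thr, tdi$grid)
}

#' Sum binarized subject maps into a raw maximum probability map
#'
#' @param template_masks list of `n >= 1` [vox_mask()] objects on a common
#'   grid.
#' @return A list with `values` (integer array, voxelwise count of subjects,
#'   bounded by `n`), `grid` and `n_subjects`.
#' @export
build_mpm <- function(template_masks) {
  n <- length(template_masks)
  if (n < 1) stop("build_mpm needs at least one mask")
  g <- template_masks[[1]]$grid
  acc <- array(0L, g$dim)
  for (m in template_masks) {
    if (!same_grid(m$grid, g)) stop("build_mpm: grid mismatch")
    acc <- acc + m$data
  }
  list(values = acc, grid = g, n_subjects = n)
}

#' z-score a maximum probability map
#'
#' Subtracts the mean and divides by the standard deviation of the map over
#' the chosen domain (all voxels, or nonzero voxels only); voxels outside the
#' domain are set to `background`.
#'
#' @param mpm a [build_mpm()] result.
#' @param domain `"all_voxels"` or `"nonzero"`.
#' @param background value recorded outside the domain (default 0 for the
#'   all-voxel domain, which has no outside).
#' @return A list with `values` (numeric array), `grid`, `domain`,
#'   `background`, and the `mean` and `sd` used.
#' @export
zscore_map <- function(mpm, domain = c("all_voxels", "nonzero"),
                       background = 0) {
  domain <- match.arg(domain)
  v <- mpm$values
  in_dom <- if (domain == "nonzero") v != 0 else array(TRUE, dim(v))
  mu <- mean(v[in_dom])
  sd <- sqrt(mean((v[in_dom] - mu)^2)) # population sd: {0,2} maps to {-1,+1}
  if (!is.finite(sd) || sd == 0)
    stop("zscore_map: zero standard deviation over the chosen domain")
  z <- array(background, dim(v))
  z[in_dom] <- (v[in_dom] - mu) / sd
  list(values = z, grid = mpm$grid, domain = domain, background = background,
       mean = mu, sd = sd)
}

#' Atlas subject accounting
#'
#' Number of subjects entering the atlas: the main dataset plus the test
#' scans of test-retest subjects that are not already part of the main
#' dataset (210 + (44 - 11) = 243 for the cohort composition the atlas
#' mirrors).
#'
#' @param n_main main-dataset size.
#' @param n_retest test-retest dataset size.
#' @param n_overlap subjects in both datasets.
#' @return Integer subject count.
#' @export
atlas_subject_count <- function(n_main = 210, n_retest = 44, n_overlap = 11) {
  if (n_overlap > min(n_main, n_retest))
    stop("overlap cannot exceed either dataset")
  as.integer(n_main + (n_retest - n_overlap))
}

#' Build a z-scored probabilistic tract atlas from template-space masks
#'
#' @param template_masks named-by-subject list of binarized template-space
#'   tract maps.
#' @param tract tract label.
#' @param domain z-scoring domain, see [zscore_map()].
#' @return An object of class `"mpm_atlas"` with the raw count map, the
#'   z-scored map and provenance fields.
#' @export
build_atlas <- function(template_masks, tract, domain = "all_voxels") {
  mpm <- build_mpm(template_masks)
  z <- zscore_map(mpm, domain)
  structure(list(tract = tract, raw = mpm, z = z,
                 n_subjects = mpm$n_subjects), class = "mpm_atlas")
}

#' @export
print.mpm_atlas <- function(x, ...) {
  cat(sprintf("<mpm_atlas> %s: %d subjects, raw max %d, z range [%.2f, %.2f]\n",
              x$tract, x$n_subjects, max(x$raw$values), min(x$z$values),
              max(x$z$values)))
  invisible(x)
}

#' Export an atlas as NIfTI volumes plus a JSON sidecar
#'
#' Writes `<tract>_mpm.nii.gz` (raw integer counts) and `<tract>_z.nii.gz`
#' (z-scored) into `dir`, and a sidecar `<tract>_atlas.json` recording the
#' subject count, the tracking configuration provenance and the seed.
#'
#' @param atlas an `"mpm_atlas"`.
#' @param dir output directory.
#' @param config optional [track_config()] recorded as provenance.
#' @param seed optional integer seed recorded as provenance.
#' @param space_label template-space identifier written to the sidecar.
#' @return Named character vector of the files written, invisibly.
#' @export
export_atlas <- function(atlas, dir, config = NULL, seed = NULL,
                         space_label = "phantom-template") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  raw_path <- file.path(dir, sprintf("%s_mpm.nii.gz", atlas$tract))
  z_path <- file.path(dir, sprintf("%s_z.nii.gz", atlas$tract))
  arr <- atlas$raw$values
  storage.mode(arr) <- "integer"
  write_volume_nifti(arr, atlas$raw$grid, raw_path)
  write_volume_nifti(atlas$z$values, atlas$z$grid, z_path)
  sidecar <- list(tract = atlas$tract, n_subjects = atlas$n_subjects,
                  space = space_label,
                  zscore_domain = atlas$z$domain,
                  zscore_mean = atlas$z$mean, zscore_sd = atlas$z$sd)
  if (!is.null(config))
    sidecar$config <- list(algorithm = config$algorithm,
                           step_size = config$step_size,
                           angle_threshold = config$angle_threshold,
                           cutoff = config$cutoff)
  if (!is.null(seed)) sidecar$seed <- seed
  json_path <- file.path(dir, sprintf("%s_atlas.json", atlas$tract))
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(raw = raw_path, z = z_path, sidecar = json_path))
}
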