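#' Pipeline configuration
#'
#' Validates and materializes a pipeline configuration (defaults filled in,
#' all seeds explicit), either from a YAML file or from an R list. Fields:
#' `n_subjects`, `n_retest`, `warp_amplitude`, `warp_smoothness`,
#' `amplitude_noise_sd`, `direction_noise_sd`, `tracts`,
#' `streamlines_per_roi`, `cutoff`, `binarize_fraction`, `out_dir`,
#' `rng_seed`.
#'
#' @param config list or path to a YAML file.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(n_subjects = 20L, n_retest = NULL, warp_amplitude = 2,
                   warp_smoothness = 8, amplitude_noise_sd = 0.05,
                   direction_noise_sd = 5, tracts = NULL,
                   streamlines_per_roi = 25L, cutoff = 0.05,
                   binarize_fraction = 0.15, out_dir = "tractopt-out",
                   rng_seed = 1L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown pipeline config field(s): %s",
                 paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  cfg$n_retest <- cfg$n_retest %||% min(5L, cfg$n_subjects)
  if (cfg$n_retest > cfg$n_subjects)
    stop("invalid pipeline config: n_retest > n_subjects")
  if (cfg$binarize_fraction <= 0 || cfg$binarize_fraction >= 1)
    stop("invalid pipeline config: binarize_fraction must be in (0, 1)")
  cfg$n_subjects <- as.integer(cfg$n_subjects)
  cfg$n_retest <- as.integer(cfg$n_retest)
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  structure(cfg, class = "pipeline_config")
}

provenance_block <- function(cfg) {
  list(package = "tractopt",
       version = as.character(utils::packageVersion("tractopt")),
       rng_seed = cfg$rng_seed,
       config_hash = digest_config(cfg))
}

# Small content hash of the materialized config (provenance only).
digest_config <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x), collapse = ","), character(1)), collapse = ";")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", h)
}

#' Simulate and write a phantom cohort (pipeline stage 1)
#'
#' Builds the default subthalamic-like phantom, generates the cohort, and
#' writes template field, subject fields, warps, ground-truth masks, ROIs and
#' a YAML manifest to `cfg$out_dir/cohort`.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with the in-memory `phantom` and `cohort` and
#'   the manifest path.
#' @export
pipeline_simulate <- function(cfg = pipeline_config()) {
  cfg <- pipeline_config(unclass(cfg))
  phantom <- default_phantom()
  spec <- cohort_spec(n_subjects = cfg$n_subjects, n_retest = cfg$n_retest,
                      warp_amplitude = cfg$warp_amplitude,
                      warp_smoothness = cfg$warp_smoothness,
                      amplitude_noise_sd = cfg$amplitude_noise_sd,
                      direction_noise_sd = cfg$direction_noise_sd,
                      rng_seed = derive_seed(cfg$rng_seed, "cohort"))
  cohort <- make_cohort(phantom$field, spec)
  dir <- file.path(cfg$out_dir, "cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_field_nifti(phantom$field, file.path(dir, "template"))
  for (tract in names(phantom$truth)) {
    write_mask_nifti(phantom$truth[[tract]],
                     file.path(dir, sprintf("truth_%s.nii.gz", tract)))
    for (r in seq_along(phantom$rois[[tract]]))
      write_mask_nifti(phantom$rois[[tract]][[r]],
                       file.path(dir, sprintf("roi_%s_%d.nii.gz", tract, r)))
  }
  manifest <- write_cohort(cohort, dir)
  m <- yaml::read_yaml(manifest)
  m$provenance <- provenance_block(cfg)
  yaml::write_yaml(m, manifest)
  invisible(list(phantom = phantom, cohort = cohort, manifest = manifest))
}

#' Run the optimization stage (pipeline stage 2)
#'
#' Evaluates the full 34-configuration grid on the cohort and writes the
#' score-card CSV and the selected best configurations as YAML to
#' `cfg$out_dir`.
#'
#' @param cfg a [pipeline_config()].
#' @param sim optional result of [pipeline_simulate()] (regenerated from the
#'   config when missing, which is cheap and reproducible).
#' @return The `"tract_opt"` fit, invisibly.
#' @export
pipeline_optimize <- function(cfg = pipeline_config(), sim = NULL) {
  cfg <- pipeline_config(unclass(cfg))
  sim <- sim %||% pipeline_simulate(cfg)
  tracts <- cfg$tracts %||% names(sim$phantom$truth)
  fit <- tract_optimize(sim$cohort, sim$phantom, tracts = tracts,
                        grid = build_grid(cutoff = cfg$cutoff),
                        base_seed = derive_seed(cfg$rng_seed, "optimize"),
                        streamlines_per_roi = cfg$streamlines_per_roi,
                        binarize_fraction = cfg$binarize_fraction)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_opt_report(fit, file.path(cfg$out_dir, "scorecards.csv"),
                   file.path(cfg$out_dir, "best_configs.yaml"))
  invisible(fit)
}

#' Build and export the atlases (pipeline stage 3)
#'
#' Re-tracks every subject with each tract's best-working configuration,
#' aggregates the binarized template-space maps into raw and z-scored maximum
#' probability maps, and exports them as NIfTI plus JSON sidecars under
#' `cfg$out_dir/atlas`.
#'
#' @param cfg a [pipeline_config()].
#' @param fit a `"tract_opt"` fit from [pipeline_optimize()].
#' @param sim optional result of [pipeline_simulate()].
#' @return Named list of `"mpm_atlas"` objects, invisibly.
#' @export
pipeline_atlas <- function(cfg, fit, sim = NULL) {
  cfg <- pipeline_config(unclass(cfg))
  sim <- sim %||% pipeline_simulate(cfg)
  out <- list()
  for (tract in names(fit$best)) {
    config <- fit$best[[tract]]
    res <- evaluate_config(sim$cohort, sim$phantom, tract, config,
                           base_seed = derive_seed(cfg$rng_seed, "atlas"),
                           binarize_fraction = cfg$binarize_fraction)
    # atlas subjects: all main-dataset test maps plus retest maps of
    # subjects not contributing a test map (none here by construction)
    atlas <- build_atlas(res$test_maps, tract)
    export_atlas(atlas, file.path(cfg$out_dir, "atlas"), config = config,
                 seed = cfg$rng_seed)
    out[[tract]] <- atlas
  }
  invisible(out)
}
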