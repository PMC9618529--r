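#' Tracking configuration
#'
#' One point of the tracking-parameter space: algorithm, step size, angle
#' threshold (the maximum angle between successive step directions), and the
#' amplitude cutoff below which fixels are invisible to the tracker.
#'
#' @param algorithm `"deterministic"` (follow the most collinear supra-cutoff
#'   fixel) or `"probabilistic"` (amplitude-weighted fixel draw, then a
#'   direction sampled from a concentrated lobe distribution around that
#'   fixel, re-checked against the turn constraint).
#' @param step_size step length in mm (> 0).
#' @param angle_threshold degrees, in (0, 90].
#' @param cutoff amplitude threshold (default 0.05).
#' @param lobe_kappa concentration (von Mises-Fisher kappa) of the
#'   probabilistic lobe sampler; 15 corresponds to an angular spread of about
#'   15 degrees, a typical orientation-distribution lobe width.
#' @param min_length,max_length optional streamline length window in mm
#'   (`NA` = unset; a hard 250 mm cap always guards runaway propagation).
#' @param streamlines_per_roi accepted streamlines per seed ROI (default 250).
#' @param max_attempts seeding attempt budget (default
#'   `400 * streamlines_per_roi`).
#' @param rng_seed integer seed used by [seed_and_select()] and
#'   [short_tracks()].
#' @return An object of class `"track_config"`.
#' @export
track_config <- function(algorithm = c("deterministic", "probabilistic"),
                         step_size = 0.5, angle_threshold = 45,
                         cutoff = 0.05, lobe_kappa = 15,
                         min_length = NA, max_length = NA,
                         streamlines_per_roi = 250L,
                         max_attempts = 400L * streamlines_per_roi,
                         rng_seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (step_size <= 0) stop("step_size must be > 0")
  if (angle_threshold <= 0 || angle_threshold > 90)
    stop("angle_threshold must be in (0, 90]")
  if (cutoff < 0) stop("cutoff must be >= 0")
  structure(list(algorithm = algorithm, step_size = step_size,
                 angle_threshold = angle_threshold, cutoff = cutoff,
                 lobe_kappa = lobe_kappa,
                 min_length = min_length, max_length = max_length,
                 streamlines_per_roi = as.integer(streamlines_per_roi),
                 max_attempts = as.integer(max_attempts),
                 rng_seed = as.integer(rng_seed)),
            class = "track_config")
}

#' @export
print.track_config <- function(x, ...) {
  cat(sprintf("<track_config> %s, step %.2f mm, angle %g deg, cutoff %g\n",
              x$algorithm, x$step_size, x$angle_threshold, x$cutoff))
  invisible(x)
}

config_label <- function(cfg) {
  sprintf("%s_s%.2f_a%g", substr(cfg$algorithm, 1, 4), cfg$step_size,
          cfg$angle_threshold)
}

same_config <- function(a, b) {
  identical(a$algorithm, b$algorithm) && a$step_size == b$step_size &&
    a$angle_threshold == b$angle_threshold && a$cutoff == b$cutoff
}

algo_code <- function(cfg) if (cfg$algorithm == "deterministic") 0L else 1L

HARD_LENGTH_CAP <- 250 # mm; guards infinite loops in subject-level tracking

#' Propagate one streamline from a seed point
#'
#' Bidirectional Euler propagation: two half-tracks are grown from the seed
#' (initial heading from the seed voxel's largest-amplitude fixel, or an
#' amplitude-weighted draw for the probabilistic algorithm) and joined,
#' sharing the seed point once. At each step the candidate set is the fixels
#' of the current voxel with amplitude >= cutoff and angle to the current
#' heading <= the threshold; propagation terminates when the set is empty, on
#' grid exit, or at the length budget.
#'
#' @param field an [orientation_field()].
#' @param seed mm coordinates (length 3).
#' @param config a [track_config()].
#' @return A points matrix (n x 3, mm) with attribute `"seed_index"`, or
#'   `NULL` as a rejection signal when the seed lies outside the grid or in a
#'   voxel with no supra-cutoff fixel (callers re-seed rather than error).
#' @export
propagate <- function(field, seed, config) {
  max_len <- if (!is.na(config$max_length)) config$max_length else
    HARD_LENGTH_CAP
  out <- cpp_track(field$dirs, field$amps, field$nfix, field$grid$dim,
                   field$grid$vox, field$grid$origin, as.numeric(seed),
                   algo_code(config), config$step_size,
                   config$angle_threshold, config$cutoff, max_len,
                   config$lobe_kappa %||% 15)
  out
}

new_tractogram <- function(streamlines, config, tract_name = "",
                           seed_roi_ids = character(0)) {
  structure(list(streamlines = streamlines, config = config,
                 tract_name = tract_name, seed_roi_ids = seed_roi_ids),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, integer(1))
  cat(sprintf("<tractogram> '%s': %d streamlines, %d-%d points, %s step %.2f\n",
              x$tract_name, length(np), if (length(np)) min(np) else 0,
              if (length(np)) max(np) else 0, x$config$algorithm,
              x$config$step_size))
  invisible(x)
}

#' Seed-based, waypoint-constrained tract selection
#'
#' Draws uniform random seed points within the seed-ROI voxels and keeps a
#' streamline iff it intersects every inclusion ROI, intersects no exclusion
#' mask, and satisfies the configured length window, until
#' `streamlines_per_roi` streamlines are accepted or the attempt budget is
#' exhausted.
#'
#' @param field an [orientation_field()].
#' @param seed_roi nonempty [vox_mask()] to seed from.
#' @param include_rois list of [vox_mask()] inclusion regions.
#' @param exclude_masks list of [vox_mask()] exclusion regions (may be empty).
#' @param config a [track_config()]; `config$rng_seed` makes the accepted set
#'   and its order deterministic.
#' @param tract_name,seed_roi_id labels recorded in the tractogram.
#' @return A tractogram with exactly `streamlines_per_roi`
#'   streamlines.
#' @export
seed_and_select <- function(field, seed_roi, include_rois = list(),
                            exclude_masks = list(), config = track_config(),
                            tract_name = "", seed_roi_id = "roi") {
  sv <- mask_indices(seed_roi)
  if (nrow(sv) == 0) stop("seed ROI is empty")
  excl <- if (length(exclude_masks)) {
    acc <- exclude_masks[[1]]$data
    for (m in exclude_masks[-1]) acc <- acc | m$data
    as.logical(acc)
  } else logical(0)
  set.seed(config$rng_seed)
  res <- cpp_seed_select(field$dirs, field$amps, field$nfix, field$grid$dim,
                         field$grid$vox, field$grid$origin, sv,
                         lapply(include_rois, to_logical_vec), excl,
                         algo_code(config), config$step_size,
                         config$angle_threshold, config$cutoff,
                         ifelse(is.na(config$min_length), -1,
                                config$min_length),
                         ifelse(is.na(config$max_length), -1,
                                config$max_length),
                         HARD_LENGTH_CAP, config$streamlines_per_roi,
                         config$max_attempts, config$lobe_kappa %||% 15)
  if (res$accepted < config$streamlines_per_roi)
    stop(sprintf(
      "seed_and_select('%s'/%s): only %d of %d streamlines accepted in %d attempts (acceptance rate %.4f)",
      tract_name, seed_roi_id, res$accepted, config$streamlines_per_roi,
      res$attempts, res$accepted / res$attempts))
  tg <- new_tractogram(res$streamlines, config, tract_name, seed_roi_id)
  attr(tg, "attempts") <- res$attempts
  tg
}

#' Short-tracks seeding over a mask
#'
#' Probabilistic whole-mask seeding of many short streamlines, the substrate
#' of super-resolution track-density imaging: every returned streamline has
#' arc length within `[min_length, max_length]` mm (tracks are truncated at
#' the maximum by the propagation length budget; shorter tracks are
#' discarded).
#'
#' @param field an [orientation_field()].
#' @param mask nonempty [vox_mask()] seeding region.
#' @param n_tracks number of streamlines to return.
#' @param config a [track_config()]; defaults follow the short-tracks recipe
#'   (probabilistic, step 0.25 mm, cutoff 0.05, lengths 5-10 mm).
#' @param max_attempts attempt budget (default `50 * n_tracks`).
#' @return A tractogram.
#' @export
short_tracks <- function(field, mask, n_tracks,
                         config = track_config("probabilistic",
                                               step_size = 0.25,
                                               angle_threshold = 45,
                                               cutoff = 0.05,
                                               min_length = 5,
                                               max_length = 10),
                         max_attempts = 50L * n_tracks) {
  sv <- mask_indices(mask)
  if (nrow(sv) == 0) stop("short_tracks: mask is empty")
  set.seed(config$rng_seed)
  res <- cpp_short_tracks(field$dirs, field$amps, field$nfix, field$grid$dim,
                          field$grid$vox, field$grid$origin, sv,
                          algo_code(config), config$step_size,
                          config$angle_threshold, config$cutoff,
                          config$min_length %||% 5,
                          config$max_length %||% 10,
                          as.integer(n_tracks), as.integer(max_attempts),
                          config$lobe_kappa %||% 15)
  if (res$accepted < n_tracks)
    stop(sprintf("short_tracks: only %d of %d tracks in %d attempts",
                 res$accepted, n_tracks, res$attempts))
  new_tractogram(res$streamlines, config, "short_tracks")
}

#' Concatenate tractograms of one tract
#'
#' Order-preserving union of the streamlines of several tractograms sharing
#' the same tract name and configuration (the per-waypoint-ROI tractograms of
#' one tract are concatenated into its final tractogram).
#'
#' @param tractograms nonempty list of tractograms.
#' @return A single tractogram.
#' @export
concat_tractograms <- function(tractograms) {
  if (length(tractograms) == 0) stop("concat_tractograms: empty input list")
  t1 <- tractograms[[1]]
  for (t in tractograms[-1]) {
    if (!identical(t$tract_name, t1$tract_name) ||
        !same_config(t$config, t1$config))
      stop("concat_tractograms: mixed tract names or configurations")
  }
  new_tractogram(do.call(c, lapply(tractograms, `[[`, "streamlines")),
                 t1$config, t1$tract_name,
                 unlist(lapply(tractograms, `[[`, "seed_roi_ids")))
}

## ---- TCK I/O ---------------------------------------------------------------

#' Write a tractogram in TCK format
#'
#' MRtrix-style track file: a text header (`mrtrix tracks` magic, key: value
#' lines including step size, count and the RNG seed as a comment), then
#' little-endian float32 triplets with NaN streamline separators and an Inf
#' terminator.
#'
#' @param tractogram a tractogram.
#' @param path output `.tck` path.
#' @export
write_tck <- function(tractogram, path) {
  n <- length(tractogram$streamlines)
  offset <- 512L # fixed data offset; header is padded up to it
  hdr <- c("mrtrix tracks",
           sprintf("count: %d", n),
           sprintf("step_size: %g", tractogram$config$step_size),
           "datatype: Float32LE",
           sprintf("comment: rng_seed=%d tract=%s",
                   tractogram$config$rng_seed, tractogram$tract_name),
           sprintf("file: . %d", offset),
           "END\n")
  hdr_txt <- paste(hdr, collapse = "\n")
  nb <- nchar(hdr_txt, type = "bytes")
  if (nb > offset) stop("TCK header exceeds the fixed data offset")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr_txt, con, eos = NULL)
  if (nb < offset) writeBin(as.raw(rep(10L, offset - nb)), con)
  for (s in tractogram$streamlines) {
    writeBin(as.vector(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a TCK track file
#' @param path `.tck` file path.
#' @return A list with `streamlines` (list of n x 3 matrices) and `header`
#'   (named character vector).
#' @export
read_tck <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  end_at <- grepRaw("\nEND\n", raw_all, fixed = TRUE)
  if (length(end_at) == 0) stop("not a TCK file (no END marker)")
  hdr_lines <- strsplit(rawToChar(raw_all[seq_len(end_at - 1)]), "\n")[[1]]
  if (hdr_lines[1] != "mrtrix tracks") stop("not a TCK file")
  kv <- grep(":", hdr_lines, value = TRUE)
  keys <- sub(":.*", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  header <- stats::setNames(vals, keys)
  offset <- as.integer(strsplit(trimws(header[["file"]]), " ")[[1]][2])
  body <- raw_all[(offset + 1):length(raw_all)]
  vals <- readBin(body, "numeric", n = length(body) / 4, size = 4,
                  endian = "little")
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  is_sep <- is.nan(m[, 1])
  is_end <- is.infinite(m[, 1])
  streams <- list()
  start <- 1
  for (i in seq_len(nrow(m))) {
    if (is_sep[i] || is_end[i]) {
      if (i > start)
        streams[[length(streams) + 1]] <- m[start:(i - 1), , drop = FALSE]
      start <- i + 1
      if (is_end[i]) break
    }
  }
  list(streamlines = streams, header = header)
}
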