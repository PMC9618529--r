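GRID_STEPS <- c(0.25, 0.5, 1, 1.25)
GRID_ANGLES <- c(20, 30, 60, 80)

#' The 34-configuration tracking-parameter grid
#'
#' Per algorithm: its default configuration (deterministic: step 0.1 mm,
#' angle 60 deg; probabilistic: step 0.5 mm, angle 45 deg) plus the full cross
#' of step sizes \{0.25, 0.5, 1, 1.25\} mm and angle thresholds
#' \{20, 30, 60, 80\} deg - 17 + 17 = 34 combinations. Canonical order:
#' deterministic before probabilistic, default first, then step-major /
#' angle-minor ascending. The canonical order is also the tie-break order of
#' [select_best()].
#'
#' @param cutoff amplitude cutoff shared by all configurations.
#' @param streamlines_per_roi streamline budget per seed ROI.
#' @return List of 34 [track_config()] objects with a `"grid_index"`
#'   attribute each.
#' @export
build_grid <- function(cutoff = 0.05, streamlines_per_roi = 250L) {
  cfgs <- list()
  for (alg in c("deterministic", "probabilistic")) {
    defaults <- if (alg == "deterministic") c(0.1, 60) else c(0.5, 45)
    cfgs[[length(cfgs) + 1]] <- track_config(alg, defaults[1], defaults[2],
                                             cutoff = cutoff,
                                             streamlines_per_roi =
                                               streamlines_per_roi)
    for (s in GRID_STEPS) for (a in GRID_ANGLES)
      cfgs[[length(cfgs) + 1]] <- track_config(alg, s, a, cutoff = cutoff,
                                               streamlines_per_roi =
                                                 streamlines_per_roi)
  }
  key <- vapply(cfgs, function(cf)
    paste(cf$algorithm, cf$step_size, cf$angle_threshold), character(1))
  if (anyDuplicated(key)) stop("parameter grid contains duplicates")
  for (i in seq_along(cfgs)) attr(cfgs[[i]], "grid_index") <- i
  cfgs
}

## ---- per-subject evaluation contexts --------------------------------------

# Precompute everything about (cohort x tract) that does not depend on the
# tracking configuration: subject-space seed/inclusion ROIs, the pooled
# exclusion mask, and the nearest-neighbour pullback index used to warp
# binarized subject tract maps to template space.
tract_contexts <- function(cohort, phantom, tract,
                           expand_up = 2L, expand_down = 2L) {
  grid <- cohort$grid
  rois_t <- lapply(phantom$rois[[tract]], expand_roi, n_up = expand_up,
                   n_down = expand_down)
  truth <- phantom$truth[[tract]]
  other <- setdiff(names(phantom$rois), tract)
  excl_t <- list()
  for (o in other) for (r in phantom$rois[[o]]) {
    re <- expand_roi(r, expand_up, expand_down)
    # an exclusion ROI that cuts through this tract's own course would veto
    # every correct streamline; drop those (shared-corridor geometry)
    if (sum(re$data & truth$data) == 0) excl_t[[length(excl_t) + 1]] <- re
  }
  # whole internal-capsule-analogue bundle as exclusion for the other tracts,
  # minus any overlap with this tract's own course (crossing region)
  ic <- phantom$ic_tract %||% NULL
  if (!is.null(ic) && !identical(ic, tract)) {
    ic_excl <- vox_mask(phantom$truth[[ic]]$data & !truth$data, grid)
    if (sum(ic_excl$data) > 0) excl_t[[length(excl_t) + 1]] <- ic_excl
  }
  d <- grid$dim
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  x <- grid_mm(grid, idx)
  lapply(cohort$subjects, function(s) {
    zero_warp <- all(s$warp_from_template == 0)
    if (zero_warp) {
      seed_rois <- rois_t
      excl <- excl_t
      tmpl_src <- seq_len(prod(d))
      tmpl_ok <- rep(TRUE, prod(d))
    } else {
      vdisp <- s$warp_to_template
      seed_rois <- lapply(rois_t, warp_mask, displacement = vdisp,
                          target_grid = grid)
      excl <- lapply(excl_t, warp_mask, displacement = vdisp,
                     target_grid = grid)
      src <- x + matrix(s$warp_from_template, ncol = 3)
      sv <- grid_voxel(grid, src)
      tmpl_ok <- in_grid(grid, sv)
      sv[, 1] <- pmin(pmax(sv[, 1], 1L), d[1])
      sv[, 2] <- pmin(pmax(sv[, 2], 1L), d[2])
      sv[, 3] <- pmin(pmax(sv[, 3], 1L), d[3])
      tmpl_src <- sv[, 1] + d[1] * ((sv[, 2] - 1) + d[2] * (sv[, 3] - 1))
    }
    excl_data <- if (length(excl)) {
      acc <- excl[[1]]$data
      for (m in excl[-1]) acc <- acc | m$data
      acc
    } else array(FALSE, d)
    list(subject_id = s$subject_id, field = s$field,
         field_retest = s$field_retest, seed_rois = seed_rois,
         exclude = vox_mask(excl_data, grid), tmpl_src = tmpl_src,
         tmpl_ok = tmpl_ok)
  })
}

# Track one subject replicate under one configuration and return the
# binarized tract map warped to template space (NULL on tracking failure).
track_subject_map <- function(ctx, field, config, grid, binarize_fraction,
                              rng_seed) {
  tgs <- vector("list", length(ctx$seed_rois))
  for (r in seq_along(ctx$seed_rois)) {
    cfg <- config
    cfg$rng_seed <- derive_seed(rng_seed, "roi", r)
    tg <- tryCatch(
      seed_and_select(field, ctx$seed_rois[[r]],
                      include_rois = ctx$seed_rois[-r],
                      exclude_masks = list(ctx$exclude), config = cfg,
                      tract_name = "", seed_roi_id = sprintf("roi%d", r)),
      error = function(e) NULL)
    if (is.null(tg)) return(NULL)
    tgs[[r]] <- tg
  }
  tract <- concat_tractograms(tgs)
  tdi <- count_map(tract, grid, 1L)
  m <- binarize_tdi(tdi)
  flat <- as.logical(m$data)[ctx$tmpl_src]
  flat[!ctx$tmpl_ok] <- FALSE
  vox_mask(array(flat, grid$dim), grid)
}

#' Evaluate one tracking configuration on a cohort
#'
#' Per subject: track the tract (250 streamlines per waypoint ROI by default,
#' the other waypoint ROIs as inclusion masks, other tracts' ROIs as
#' exclusion masks), convert to a track-density map, binarize at 15% of the
#' maximum streamline density and warp to template space; then score
#' anatomical accuracy against the reference delineation, within-subject
#' (test-retest) and between-subject Dice similarity, and their unweighted
#' mean. Subjects whose tracking fails (streamline budget not reached) are
#' excluded with a count; more than 50% failures fails the configuration.
#'
#' @param cohort a [make_cohort()] result.
#' @param phantom a [default_phantom()]-shaped list (grid, truth, rois).
#' @param tract tract name to evaluate.
#' @param config a [track_config()].
#' @param base_seed integer seed for the per-(config, subject, ROI) RNG
#'   streams.
#' @param binarize_fraction TDI binarization threshold as a fraction of the
#'   map maximum (default 0.15).
#' @param contexts optional precomputed `tract_contexts()` result (shared
#'   across configurations for speed).
#' @return A list with the `"score_card"`, `n_failed`, and the template-space
#'   maps, or an error if more than half the subjects fail.
#' @export
evaluate_config <- function(cohort, phantom, tract, config, base_seed = 1L,
                            binarize_fraction = 0.15, contexts = NULL) {
  ctxs <- contexts %||% tract_contexts(cohort, phantom, tract)
  grid <- cohort$grid
  gi <- attr(config, "grid_index") %||% 0L
  test_maps <- list()
  retest_maps <- list()
  n_failed <- 0L
  for (si in seq_along(ctxs)) {
    ctx <- ctxs[[si]]
    seed_s <- derive_seed(base_seed, "cfg", gi, config$algorithm,
                          round(config$step_size * 100),
                          round(config$angle_threshold), "sub", si)
    # test and retest replicates share the tracking seed (same protocol on
    # the same subject; only the data differ), so a noise-free cohort gives
    # within-subject Dice of exactly 1
    m <- track_subject_map(ctx, ctx$field, config, grid, binarize_fraction,
                           seed_s)
    if (is.null(m)) {
      n_failed <- n_failed + 1L
      next
    }
    test_maps[[ctx$subject_id]] <- m
    if (!is.null(ctx$field_retest)) {
      m2 <- track_subject_map(ctx, ctx$field_retest, config, grid,
                              binarize_fraction, seed_s)
      if (!is.null(m2)) retest_maps[[ctx$subject_id]] <- m2
    }
  }
  if (n_failed > length(ctxs) / 2)
    stop(sprintf("evaluate_config(%s, %s): %d of %d subjects failed",
                 tract, config_label(config), n_failed, length(ctxs)))
  if (length(test_maps) < 2 || length(retest_maps) < 1)
    stop(sprintf("evaluate_config(%s, %s): too few usable subjects",
                 tract, config_label(config)))
  truth <- phantom$truth[[tract]]
  acc <- mean(vapply(test_maps, anatomical_accuracy, numeric(1),
                     manual = truth))
  ws <- within_subject(test_maps[names(retest_maps)], retest_maps)
  bs <- between_subject(unname(test_maps))
  card <- overall_score(tract, config, acc, ws, bs)
  list(card = card, n_failed = n_failed, test_maps = test_maps,
       retest_maps = retest_maps)
}

#' Select the best-working configuration from score cards
#'
#' Argmax of the overall score; exact ties are broken by canonical grid order
#' (earliest wins) with a warning. Failed configurations (NA overall) are
#' skipped.
#'
#' @param scorecards data.frame with columns `overall` and `grid_index`
#'   (one row per configuration, canonical order), as produced by
#'   [tract_optimize()].
#' @return The winning row's `grid_index`.
#' @export
select_best <- function(scorecards) {
  ok <- which(!is.na(scorecards$overall))
  if (length(ok) == 0) stop("select_best: all configurations failed")
  o <- scorecards$overall[ok]
  top <- ok[o == max(o)]
  if (length(top) > 1)
    warning(sprintf("select_best: exact tie among %d configurations; %s",
                    length(top), "keeping the earliest in canonical order"))
  scorecards$grid_index[min(top)]
}

#' Optimize tractography parameters on a phantom cohort
#'
#' The central fit: evaluates every configuration of the 34-point parameter
#' grid on every requested tract of a synthetic cohort, scoring each by the
#' mean of anatomical accuracy, within-subject and between-subject Dice
#' similarity, and selects the best-working configuration per tract.
#'
#' @param cohort a [make_cohort()] result.
#' @param phantom a [default_phantom()]-shaped list.
#' @param tracts character vector of tract names (default: all in the
#'   phantom).
#' @param grid list of configurations from [build_grid()].
#' @param base_seed integer master seed; every (configuration, subject, ROI)
#'   combination derives its own stream from it.
#' @param streamlines_per_roi per-ROI streamline budget applied to every
#'   configuration.
#' @param binarize_fraction TDI binarization fraction (default 0.15).
#' @param verbose print one line per configuration.
#' @return An object of class `"tract_opt"` with components `scores` (one
#'   data.frame row per tract x configuration), `best` (named list of winning
#'   [track_config()]s), `grid`, and the evaluation settings.
#' @export
tract_optimize <- function(cohort, phantom, tracts = names(phantom$truth),
                           grid = build_grid(), base_seed = 1L,
                           streamlines_per_roi = 25L,
                           binarize_fraction = 0.15, verbose = FALSE) {
  rows <- list()
  best <- list()
  for (tract in tracts) {
    ctxs <- tract_contexts(cohort, phantom, tract)
    for (cfg in grid) {
      cfg$streamlines_per_roi <- as.integer(streamlines_per_roi)
      cfg$max_attempts <- 400L * cfg$streamlines_per_roi
      gi <- attr(cfg, "grid_index")
      res <- tryCatch(
        evaluate_config(cohort, phantom, tract, cfg, base_seed,
                        binarize_fraction, contexts = ctxs),
        error = function(e) e)
      row <- if (inherits(res, "error")) {
        data.frame(tract = tract, algorithm = cfg$algorithm,
                   step_size = cfg$step_size,
                   angle_threshold = cfg$angle_threshold, cutoff = cfg$cutoff,
                   anatomical_accuracy = NA_real_, within_subject = NA_real_,
                   between_subject = NA_real_, overall = NA_real_,
                   n_failed = NA_integer_, stringsAsFactors = FALSE)
      } else {
        score_card_row(res$card, res$n_failed)
      }
      row$grid_index <- gi
      rows[[length(rows) + 1]] <- row
      if (verbose)
        message(sprintf("%s %-14s overall=%s", tract, config_label(cfg),
                        if (is.na(row$overall)) "failed" else
                          sprintf("%.3f", row$overall)))
    }
    sc <- do.call(rbind, rows[vapply(rows, function(r) r$tract == tract,
                                     logical(1))])
    bi <- select_best(sc)
    bc <- grid[[bi]]
    bc$streamlines_per_roi <- as.integer(streamlines_per_roi)
    best[[tract]] <- bc
  }
  structure(list(scores = do.call(rbind, rows), best = best, grid = grid,
                 base_seed = base_seed,
                 streamlines_per_roi = as.integer(streamlines_per_roi),
                 binarize_fraction = binarize_fraction,
                 n_subjects = cohort$spec$n_subjects,
                 n_retest = cohort$spec$n_retest),
            class = "tract_opt")
}

#' @export
print.tract_opt <- function(x, ...) {
  cat(sprintf("Tractography optimization: %d tracts x %d configurations, %d subjects (%d retest)\n",
              length(x$best), length(x$grid), x$n_subjects, x$n_retest))
  cat("Best-working configurations:\n")
  for (tract in names(x$best)) {
    b <- x$best[[tract]]
    row <- x$scores[x$scores$tract == tract &
                      x$scores$grid_index == attr(b, "grid_index"), ]
    cat(sprintf("  %-6s %s, step %.2f mm, angle %g deg (overall %.3f)\n",
                tract, b$algorithm, b$step_size, b$angle_threshold,
                row$overall[1]))
  }
  invisible(x)
}

#' @export
summary.tract_opt <- function(object, ...) {
  s <- object$scores
  agg <- do.call(rbind, lapply(split(s, s$tract), function(d) {
    data.frame(tract = d$tract[1], n_configs = nrow(d),
               n_failed_configs = sum(is.na(d$overall)),
               best_overall = max(d$overall, na.rm = TRUE),
               median_overall = stats::median(d$overall, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(list(table = agg, best = object$best), class = "summary.tract_opt")
}

#' @export
print.summary.tract_opt <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.tract_opt <- function(object, ...) {
  do.call(rbind, lapply(names(object$best), function(tract) {
    b <- object$best[[tract]]
    data.frame(tract = tract, algorithm = b$algorithm,
               step_size = b$step_size, angle_threshold = b$angle_threshold,
               cutoff = b$cutoff, stringsAsFactors = FALSE)
  }))
}

#' Plot optimization profiles
#'
#' One panel per tract: overall score against configuration (canonical grid
#' order), deterministic and probabilistic branches drawn separately, the
#' selected configuration highlighted.
#'
#' @param x a `"tract_opt"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tract_opt <- function(x, ...) {
  tracts <- unique(x$scores$tract)
  old <- graphics::par(mfrow = c(1, length(tracts)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (tract in tracts) {
    d <- x$scores[x$scores$tract == tract, ]
    graphics::plot(d$grid_index, d$overall, type = "n",
                   xlab = "configuration (canonical order)",
                   ylab = "overall score", main = tract, ylim = c(0, 1), ...)
    for (alg in c("deterministic", "probabilistic")) {
      dd <- d[d$algorithm == alg, ]
      graphics::lines(dd$grid_index, dd$overall,
                      col = if (alg == "deterministic") "tomato3"
                      else "steelblue4")
      graphics::points(dd$grid_index, dd$overall, pch = 16, cex = 0.6,
                       col = if (alg == "deterministic") "tomato3"
                       else "steelblue4")
    }
    bi <- attr(x$best[[tract]], "grid_index")
    graphics::points(bi, d$overall[d$grid_index == bi], pch = 8, cex = 1.5)
  }
  invisible(x)
}

#' Write the optimization report
#'
#' @param fit a `"tract_opt"` object.
#' @param csv_path path for the score-card CSV (one row per tract x
#'   configuration).
#' @param yaml_path optional path for the selected best configurations as
#'   YAML.
#' @export
write_opt_report <- function(fit, csv_path, yaml_path = NULL) {
  utils::write.csv(fit$scores, csv_path, row.names = FALSE)
  if (!is.null(yaml_path)) {
    yaml::write_yaml(lapply(fit$best, function(b)
      list(algorithm = b$algorithm, step_size = b$step_size,
           angle_threshold = b$angle_threshold, cutoff = b$cutoff)),
      yaml_path)
  }
  invisible(csv_path)
}
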