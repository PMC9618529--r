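#' Dice similarity coefficient between two binary masks
#'
#' `DSC = 2|A n B| / (|A| + |B|)`, with A and B counted in voxels. 1 means
#' absolute identity, 0 no overlap. When both masks are empty the coefficient
#' is undefined and `NaN` is returned with a warning (callers exclude such
#' pairs from averages rather than silently biasing them).
#'
#' @param A,B [vox_mask()] objects on the same grid.
#' @return A number in `[0, 1]`, or `NaN` for two empty masks.
#' @export
dice <- function(A, B) {
  if (!same_grid(A$grid, B$grid)) stop("dice: masks on different grids")
  a <- sum(A$data); b <- sum(B$data)
  if (a + b == 0) {
    warning("dice undefined for two empty masks; returning NaN")
    return(NaN)
  }
  2 * sum(A$data & B$data) / (a + b)
}

#' Anatomical accuracy of a tract map
#'
#' The fraction of tract-map voxels that fall inside the reference (manual)
#' delineation: `|map n manual| / |map|`. Voxels inside the reference are
#' treated as true positives, so the measure penalizes only voxels outside it.
#'
#' @param tract_map nonempty [vox_mask()].
#' @param manual reference [vox_mask()] on the same grid.
#' @return A number in `[0, 1]`.
#' @export
anatomical_accuracy <- function(tract_map, manual) {
  if (!same_grid(tract_map$grid, manual$grid))
    stop("anatomical_accuracy: masks on different grids")
  n <- sum(tract_map$data)
  if (n == 0) stop("anatomical_accuracy undefined for an empty tract map")
  sum(tract_map$data & manual$data) / n
}

#' Within-subject (test-retest) similarity
#'
#' Mean over subjects of the Dice coefficient between the test and retest
#' binarized tract maps of the same subject. `NaN` pairs (both maps empty)
#' are excluded with a warning.
#'
#' @param test_maps,retest_maps named lists of [vox_mask()], paired by name.
#' @return Mean Dice in `[0, 1]`.
#' @export
within_subject <- function(test_maps, retest_maps) {
  ids <- names(test_maps)
  if (is.null(ids) || !setequal(ids, names(retest_maps)) ||
      length(ids) != length(retest_maps))
    stop("within_subject: test and retest maps must pair by subject id")
  if (length(ids) < 1) stop("within_subject needs at least one pair")
  d <- vapply(ids, function(i) dice(test_maps[[i]], retest_maps[[i]]),
              numeric(1))
  if (anyNA(d)) {
    warning(sprintf("within_subject: excluding %d empty-vs-empty pair(s)",
                    sum(is.na(d))))
    d <- d[!is.na(d)]
  }
  mean(d)
}

#' Between-subject similarity
#'
#' Mean Dice coefficient over all `n(n-1)/2` unordered pairs of subjects'
#' binarized tract maps in a common (template) space.
#'
#' @param maps list of `n >= 2` [vox_mask()] objects on a common grid.
#' @return Mean pairwise Dice in `[0, 1]`.
#' @export
between_subject <- function(maps) {
  n <- length(maps)
  if (n < 2) stop("between_subject needs at least 2 subjects")
  d <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d <- c(d, dice(maps[[i]], maps[[j]]))
  if (anyNA(d)) {
    warning(sprintf("between_subject: excluding %d empty-vs-empty pair(s)",
                    sum(is.na(d))))
    d <- d[!is.na(d)]
  }
  mean(d)
}

#' Combine per-hemisphere outcome measures into an overall score card
#'
#' Each of the three outcome measures (anatomical accuracy, within-subject and
#' between-subject similarity) is first averaged over the hemispheres it was
#' measured in, then the overall score is the unweighted mean of the three.
#'
#' @param tract tract label.
#' @param config the [track_config()] evaluated.
#' @param anatomical_accuracy,within_subject,between_subject numeric vectors
#'   of per-hemisphere values (length 1 for a single-hemisphere phantom).
#' @return An object of class `"score_card"`.
#' @export
overall_score <- function(tract, config, anatomical_accuracy,
                          within_subject, between_subject) {
  ms <- list(anatomical_accuracy = anatomical_accuracy,
             within_subject = within_subject,
             between_subject = between_subject)
  if (any(vapply(ms, function(m) length(m) == 0 || all(is.na(m)), logical(1))))
    stop("overall_score: every measure must be available for >= 1 hemisphere")
  hm <- vapply(ms, function(m) mean(m, na.rm = TRUE), numeric(1))
  structure(list(tract = tract, config = config,
                 anatomical_accuracy = unname(hm[1]),
                 within_subject = unname(hm[2]),
                 between_subject = unname(hm[3]),
                 overall = mean(hm)),
            class = "score_card")
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf("<score_card> %s | %s step %.2f angle %g | acc %.3f within %.3f between %.3f | overall %.3f\n",
              x$tract, x$config$algorithm, x$config$step_size,
              x$config$angle_threshold, x$anatomical_accuracy,
              x$within_subject, x$between_subject, x$overall))
  invisible(x)
}

# One-row data.frame form used for the optimization report CSV.
score_card_row <- function(x, n_failed = 0) {
  data.frame(tract = x$tract, algorithm = x$config$algorithm,
             step_size = x$config$step_size,
             angle_threshold = x$config$angle_threshold,
             cutoff = x$config$cutoff,
             anatomical_accuracy = x$anatomical_accuracy,
             within_subject = x$within_subject,
             between_subject = x$between_subject,
             overall = x$overall, n_failed = n_failed,
             stringsAsFactors = FALSE)
}
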