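test_that("deterministic tracking spans a straight tube end to end", {
  tf <- straight_tube_field(n = 20, radius = 2, amp = 1)
  cfg <- track_config("deterministic", step_size = 1, angle_threshold = 45)
  s <- propagate(tf$field, c(9.5, 9.5, 10), cfg)
  expect_false(is.null(s))
  # spans at least the fixel-bearing extent (z in [1, 18])
  expect_lte(min(s[, 3]), 2)
  expect_gte(max(s[, 3]), 17)
  d <- diff(s)
  d <- d / sqrt(rowSums(d^2))
  turns <- rowSums(d[-1, , drop = FALSE] * d[-nrow(d), , drop = FALSE])
  expect_true(all(turns > 1 - 1e-9)) # all turns are zero
  expect_equal(attr(s, "seed_index") >= 1 &&
                 attr(s, "seed_index") <= nrow(s), TRUE)
})

test_that("arc completion follows the analytic per-step turn angle", {
  # radius 2.5 mm, step 1 mm: per-step turn 2*asin(step/(2r)) = 23.07 deg,
  # so a 20-degree threshold terminates early and 30 degrees completes
  b <- bundle_spec("arc", arc = list(center = c(10, 10, 6), radius = 2.5,
                                     u = c(1, 0, 0), v = c(0, 0, 1),
                                     theta = c(0, 180)),
                   tube_radius = 0.6, amplitude = 0.8)
  g <- vox_grid(c(80, 80, 60), 0.25)
  f <- make_bundle_field(list(b), g)
  seedpt <- c(10, 10, 8.5) # arc apex
  analytic <- 2 * asin(1 / (2 * 2.5)) * 180 / pi
  expect_equal(analytic, 23.07, tolerance = 1e-3)
  s20 <- propagate(f, seedpt, track_config("deterministic", 1, 20))
  s30 <- propagate(f, seedpt, track_config("deterministic", 1, 30))
  # half-circumference is ~7.9 mm: completion needs ~7 steps
  expect_lt(nrow(s20), 5)
  expect_gte(nrow(s30), 7)
  d <- diff(s30)
  d <- d / sqrt(rowSums(d^2))
  turns <- acos(pmin(1, rowSums(d[-1, , drop = FALSE] *
                                  d[-nrow(d), , drop = FALSE]))) * 180 / pi
  expect_equal(max(turns), analytic, tolerance = 0.05 * analytic)
})

test_that("seeds in empty or out-of-grid voxels are rejected, not errors", {
  tf <- straight_tube_field(n = 20)
  cfg <- track_config("deterministic", 1, 45)
  expect_null(propagate(tf$field, c(1, 1, 10), cfg))   # zero-amplitude voxel
  expect_null(propagate(tf$field, c(50, 50, 50), cfg)) # outside grid
})

test_that("step-size and angle-threshold invariants hold over many streamlines", {
  ph <- .test_phantom()
  set.seed(41)
  n_checked <- 0
  for (alg in c("deterministic", "probabilistic")) {
    cfg <- track_config(alg, step_size = 0.7, angle_threshold = 35,
                        rng_seed = 77)
    occ <- which(ph$field$nfix > 0L, arr.ind = TRUE)
    seeds <- occ[sample(nrow(occ), 400), , drop = FALSE]
    for (i in seq_len(nrow(seeds))) {
      s <- propagate(ph$field, grid_mm(ph$grid, seeds[i, , drop = FALSE]),
                     cfg)
      if (is.null(s) || nrow(s) < 3) next
      seg <- diff(s)
      len <- sqrt(rowSums(seg^2))
      expect_lt(max(abs(len - 0.7)), 1e-6)
      d <- seg / len
      cosd <- rowSums(d[-1, , drop = FALSE] * d[-nrow(d), , drop = FALSE])
      expect_lt(max(acos(pmin(1, cosd))) * 180 / pi, 35 + 1e-6)
      n_checked <- n_checked + nrow(s)
    }
  }
  expect_gt(n_checked, 1e4) # the invariant was exercised at scale
})

test_that("deterministic propagation is seed-point-deterministic", {
  ph <- .test_phantom()
  cfg <- track_config("deterministic", 0.5, 60)
  s1 <- propagate(ph$field, c(8, 8, 20), cfg)
  s2 <- propagate(ph$field, c(8, 8, 20), cfg)
  expect_identical(s1, s2)
})

test_that("waypoint selection accepts the budget and concatenates 3 x 250", {
  tf <- straight_tube_field(n = 20, radius = 2, amp = 1)
  rois <- make_waypoint_rois(tf$bundle, tf$grid, n_rois = 3)
  cfg <- track_config("deterministic", 0.5, 45, streamlines_per_roi = 250L,
                      rng_seed = 5)
  tgs <- lapply(seq_along(rois), function(r) {
    cfg$rng_seed <- r
    seed_and_select(tf$field, rois[[r]], include_rois = rois[-r],
                    config = cfg, tract_name = "tube",
                    seed_roi_id = sprintf("roi%d", r))
  })
  expect_true(all(vapply(tgs, function(t) length(t$streamlines),
                         integer(1)) == 250L))
  all3 <- concat_tractograms(tgs)
  expect_length(all3$streamlines, 750L)
})

test_that("an exclusion mask across the tube drives acceptance to zero", {
  tf <- straight_tube_field(n = 20, radius = 2, amp = 1)
  rois <- make_waypoint_rois(tf$bundle, tf$grid, n_rois = 3)
  block <- expand_roi(rois[[2]], 1, 1) # mid-tube slab
  cfg <- track_config("deterministic", 0.5, 45, streamlines_per_roi = 10L,
                      max_attempts = 500L, rng_seed = 5)
  expect_error(
    seed_and_select(tf$field, rois[[1]], include_rois = rois[3],
                    exclude_masks = list(block), config = cfg),
    "acceptance rate")
})

test_that("selection is deterministic given the config seed", {
  tf <- straight_tube_field(n = 20)
  rois <- make_waypoint_rois(tf$bundle, tf$grid)
  cfg <- track_config("probabilistic", 0.5, 45, streamlines_per_roi = 30L,
                      rng_seed = 123)
  t1 <- seed_and_select(tf$field, rois[[1]], include_rois = rois[-1],
                        config = cfg)
  t2 <- seed_and_select(tf$field, rois[[1]], include_rois = rois[-1],
                        config = cfg)
  expect_identical(t1$streamlines, t2$streamlines)
})

test_that("short tracks honor the 5-10 mm window and point-count bounds", {
  ph <- .test_phantom()
  mask <- vox_mask(ph$field$nfix > 0L, ph$grid)
  tg <- short_tracks(ph$field, mask, n_tracks = 2000,
                     config = track_config("probabilistic", 0.25, 45,
                                           cutoff = 0.05, min_length = 5,
                                           max_length = 10, rng_seed = 8))
  lens <- vapply(tg$streamlines, function(s)
    0.25 * (nrow(s) - 1), numeric(1))
  expect_true(all(lens >= 5 - 1e-9 & lens <= 10 + 1e-9))
  npts <- vapply(tg$streamlines, nrow, integer(1))
  expect_true(all(npts >= 21L & npts <= 41L)) # length/step + 1
  expect_error(short_tracks(ph$field,
                            vox_mask(array(FALSE, ph$grid$dim), ph$grid),
                            n_tracks = 10), "empty")
})

test_that("concat refuses mixed configurations and empty input", {
  tf <- straight_tube_field(n = 16)
  cfg1 <- track_config("deterministic", 0.5, 45)
  cfg2 <- track_config("deterministic", 1, 45)
  t1 <- tractopt:::new_tractogram(list(matrix(0, 2, 3)), cfg1, "t")
  t2 <- tractopt:::new_tractogram(list(matrix(1, 2, 3)), cfg2, "t")
  expect_error(concat_tractograms(list(t1, t2)), "mixed")
  expect_error(concat_tractograms(list()), "empty")
  expect_identical(concat_tractograms(list(t1))$streamlines, t1$streamlines)
})

test_that("probabilistic high-angle tracking beats deterministic low-angle
           on the high-curvature bundle's far-ROI reach", {
  ph <- .test_phantom()
  rois <- lapply(ph$rois$AL, expand_roi, n_up = 2, n_down = 2)
  reach_fraction <- function(alg, angle) {
    cfg <- track_config(alg, step_size = 1.25, angle_threshold = angle,
                        rng_seed = 31)
    set.seed(cfg$rng_seed)
    sv <- which(rois[[1]]$data, arr.ind = TRUE)
    hit <- 0L
    n <- 300L
    for (i in seq_len(n)) {
      p <- grid_mm(ph$grid, sv[sample(nrow(sv), 1), , drop = FALSE]) +
        stats::runif(3, -0.5, 0.5)
      s <- propagate(ph$field, p, cfg)
      if (is.null(s)) next
      v <- grid_voxel(ph$grid, s)
      ok <- in_grid(ph$grid, v)
      if (any(rois[[3]]$data[v[ok, , drop = FALSE]])) hit <- hit + 1L
    }
    hit / n
  }
  f_prob80 <- reach_fraction("probabilistic", 80)
  f_det20 <- reach_fraction("deterministic", 20)
  expect_gt(f_prob80, f_det20)
})

test_that("TCK files round-trip streamlines and header metadata", {
  tf <- straight_tube_field(n = 16)
  rois <- make_waypoint_rois(tf$bundle, tf$grid)
  cfg <- track_config("deterministic", 0.5, 45, streamlines_per_roi = 5L,
                      rng_seed = 77)
  tg <- seed_and_select(tf$field, rois[[2]], include_rois = rois[-2],
                        config = cfg, tract_name = "tube")
  path <- withr::local_tempfile(fileext = ".tck")
  write_tck(tg, path)
  back <- read_tck(path)
  expect_length(back$streamlines, 5)
  expect_equal(back$header[["count"]], "5")
  expect_match(back$header[["comment"]], "rng_seed=77")
  for (i in 1:5)
    expect_equal(back$streamlines[[i]], tg$streamlines[[i]],
                 tolerance = 1e-6, ignore_attr = TRUE)
})
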