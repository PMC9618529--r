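test_that("straight tube rasterizes to axial fixels inside, nothing outside", {
  tf <- straight_tube_field(n = 20, radius = 2, amp = 1)
  f <- tf$field
  occ <- which(f$nfix > 0L, arr.ind = TRUE)
  expect_gt(nrow(occ), 0)
  # all occupied voxels within the tube, direction (0,0,1), amplitude 1
  ctr <- grid_mm(tf$grid, occ)
  expect_true(all(sqrt((ctr[, 1] - 9.5)^2 + (ctr[, 2] - 9.5)^2) <= 2 + 1e-9))
  dirm <- matrix(f$dirs, nrow = 9)
  for (i in seq_len(nrow(occ))) {
    l <- occ[i, 1] + 20 * ((occ[i, 2] - 1) + 20 * (occ[i, 3] - 1))
    expect_equal(abs(matrix(dirm[, l], 3, 3)[, 1]), c(0, 0, 1),
                 tolerance = 1e-12)
    expect_equal(f$amps[1, occ[i, 1], occ[i, 2], occ[i, 3]], 1)
  }
  # voxels far from the axis carry no fixel
  expect_equal(f$nfix[1, 1, 10], 0L)
})

test_that("quarter-arc fixels turn by 90 degrees end to end", {
  b <- quarter_arc_bundle(radius = 10, tube_radius = 1)
  grid <- vox_grid(c(30, 30, 30), 1)
  f <- make_bundle_field(list(b), grid)
  poly <- tractopt:::bundle_polyline(b)
  v_start <- grid_voxel(grid, poly[1, , drop = FALSE])
  v_end <- grid_voxel(grid, poly[nrow(poly), , drop = FALSE])
  v_mid <- grid_voxel(grid, poly[round(nrow(poly) / 2), , drop = FALSE])
  d_start <- f$dirs[, 1, v_start[1], v_start[2], v_start[3]]
  d_end <- f$dirs[, 1, v_end[1], v_end[2], v_end[3]]
  d_mid <- f$dirs[, 1, v_mid[1], v_mid[2], v_mid[3]]
  # endpoints orthogonal, midpoint at 45 deg to either (rasterized tangents)
  expect_lt(abs(sum(d_start * d_end)), 0.02)
  expect_equal(sum(d_start * d_mid), cos(pi / 4), tolerance = 0.02)
})

test_that("two bundles crossing at 90 degrees give two-fixel voxels", {
  grid <- vox_grid(c(20, 20, 20), 1)
  b1 <- bundle_spec("x", centerline = rbind(c(3, 10, 10), c(16, 10, 10)),
                    tube_radius = 1.5, amplitude = 0.8)
  b2 <- bundle_spec("y", centerline = rbind(c(10, 3, 10), c(10, 16, 10)),
                    tube_radius = 1.5, amplitude = 0.6)
  f <- make_bundle_field(list(b1, b2), grid)
  expect_equal(f$nfix[11, 11, 11], 2L)
  expect_equal(f$nfix[4, 11, 11], 1L)
  expect_equal(f$nfix[11, 4, 11], 1L)
})

test_that("centerline leaving the grid names the offending bundle", {
  grid <- vox_grid(c(10, 10, 10), 1)
  b <- bundle_spec("runaway", centerline = rbind(c(5, 5, -10), c(5, 5, 30)),
                   tube_radius = 1)
  expect_error(make_bundle_field(list(b), grid), "runaway")
  expect_error(ground_truth_mask(b, grid), "runaway")
})

test_that("ground-truth mask matches a brute-force distance check", {
  # thin tube: radius below the voxel size still yields a chain of voxels
  grid <- vox_grid(c(15, 15, 15), 1)
  b <- bundle_spec("thin", centerline = rbind(c(7, 7, 3), c(7, 7, 12)),
                   tube_radius = 0.4)
  m <- ground_truth_mask(b, grid)
  expect_gt(sum(m$data), 0)
  poly <- tractopt:::bundle_polyline(b, spacing = 0.01)
  idx <- as.matrix(expand.grid(1:15, 1:15, 1:15))
  ctr <- grid_mm(grid, idx)
  dmin <- apply(ctr, 1, function(p)
    sqrt(min(colSums((t(poly) - p)^2))))
  expect_equal(as.vector(m$data), dmin <= 0.4 + 1e-6)
})

test_that("disjoint bundles give disjoint masks", {
  grid <- vox_grid(c(20, 20, 20), 1)
  b1 <- bundle_spec("a", centerline = rbind(c(5, 5, 3), c(5, 5, 16)),
                    tube_radius = 1.5)
  b2 <- bundle_spec("b", centerline = rbind(c(14, 14, 3), c(14, 14, 16)),
                    tube_radius = 1.5)
  m1 <- ground_truth_mask(b1, grid)
  m2 <- ground_truth_mask(b2, grid)
  expect_equal(sum(m1$data & m2$data), 0)
})

test_that("waypoint ROIs are single-slice, on-course, and honor n_rois", {
  tf <- straight_tube_field(n = 20)
  rois <- make_waypoint_rois(tf$bundle, tf$grid, n_rois = 3)
  expect_length(rois, 3)
  truth <- ground_truth_mask(tf$bundle, tf$grid)
  zs <- vapply(rois, function(r) {
    idx <- which(r$data, arr.ind = TRUE)
    expect_length(unique(idx[, attr(r, "axis")]), 1)
    expect_gt(sum(r$data & truth$data), 0) # intersects ground truth
    unique(idx[, 3])
  }, numeric(1))
  # slices at 10% / 50% / 90% of the centerline arc length (z from 3 to 16)
  expect_true(all(abs(zs - c(5, 11, 16)) <= 1))
  rois2 <- make_waypoint_rois(tf$bundle, tf$grid, n_rois = 2)
  expect_length(rois2, 2)
  expect_lt(max(abs(vapply(rois2, attr, numeric(1), "slice") - c(5, 15))), 2)
  expect_error(make_waypoint_rois(tf$bundle, tf$grid, n_rois = 1), "n_rois")
})

test_that("zero-warp zero-noise cohorts reproduce the template exactly", {
  tf <- straight_tube_field(n = 14)
  spec <- cohort_spec(n_subjects = 3, warp_amplitude = 0,
                      amplitude_noise_sd = 0, direction_noise_sd = 0,
                      n_retest = 1, rng_seed = 5)
  co <- make_cohort(tf$field, spec)
  expect_length(co$subjects, 3)
  for (s in co$subjects) {
    expect_equal(s$field$amps, tf$field$amps)
    expect_equal(s$field$dirs, tf$field$dirs)
  }
  # retest replicate identical too (so downstream within-subject Dice is 1)
  expect_equal(co$subjects[[1]]$field_retest$amps, tf$field$amps)
})

test_that("cohort generation is a pure function of (template, spec)", {
  tf <- straight_tube_field(n = 14)
  spec <- cohort_spec(n_subjects = 2, warp_amplitude = 1.5,
                      warp_smoothness = 6, n_retest = 1, rng_seed = 9)
  co1 <- make_cohort(tf$field, spec)
  co2 <- make_cohort(tf$field, spec)
  expect_identical(co1$subjects[[1]]$field$amps, co2$subjects[[1]]$field$amps)
  expect_identical(co1$subjects[[1]]$field$dirs, co2$subjects[[1]]$field$dirs)
  expect_identical(co1$subjects[[2]]$warp_from_template,
                   co2$subjects[[2]]$warp_from_template)
  expect_identical(co1$subjects[[1]]$field_retest$amps,
                   co2$subjects[[1]]$field_retest$amps)
})

test_that("warp reorientation preserves unit norms and round-trips masks", {
  ph <- .test_phantom()
  spec <- cohort_spec(n_subjects = 2, warp_amplitude = 2, warp_smoothness = 8,
                      amplitude_noise_sd = 0, direction_noise_sd = 0,
                      n_retest = 0, rng_seed = 3)
  co <- make_cohort(ph$field, spec)
  warped_dice <- numeric(0)
  for (s in co$subjects) {
    f <- s$field
    nf <- as.vector(f$nfix)
    occ <- rep(1:3, times = length(nf)) <= rep(nf, each = 3)
    nrm <- sqrt(colSums(matrix(f$dirs, nrow = 3)^2))
    expect_lt(max(abs(nrm[occ] - 1)), 1e-6)
    # truth mask warped to subject space and back: Dice >= 0.9
    truth <- ph$truth$MTT
    warped <- warp_mask(truth, s$warp_to_template, ph$grid)
    back <- warp_mask(warped, s$warp_from_template, ph$grid)
    expect_gte(dice(back, truth), 0.9)
    warped_dice <- c(warped_dice, dice(warped, truth))
  }
  # the warp visibly displaces the tract in at least one subject (it can be
  # sub-voxel near a given bundle for an individual draw)
  expect_lt(min(warped_dice), 1)
})

test_that("cohort spec validation rejects inconsistent settings", {
  expect_error(cohort_spec(n_subjects = 2, n_retest = 3), "n_retest")
  expect_error(cohort_spec(warp_smoothness = 0), "smoothness")
  expect_error(cohort_spec(amplitude_noise_sd = -1), "noise")
})

test_that("cohort manifest round-trips through disk", {
  tf <- straight_tube_field(n = 12)
  spec <- cohort_spec(n_subjects = 2, warp_amplitude = 1, warp_smoothness = 5,
                      n_retest = 1, rng_seed = 2)
  co <- make_cohort(tf$field, spec)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  m <- yaml::read_yaml(manifest)
  expect_equal(m$n_subjects, 2)
  expect_length(m$subjects, 2)
  f2 <- read_field_nifti(file.path(dir, "sub-001"))
  expect_equal(f2$amps, co$subjects[[1]]$field$amps, tolerance = 1e-6)
  expect_equal(f2$nfix, co$subjects[[1]]$field$nfix)
})
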