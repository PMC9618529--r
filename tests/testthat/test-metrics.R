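mask_of <- function(grid, idx) mask_from_indices(idx, grid)

test_that("dice: identity, disjoint, arithmetic, symmetry, NaN convention", {
  grid <- vox_grid(c(10, 10, 10), 1)
  A <- mask_of(grid, cbind(1:5, 1, 1))
  B <- mask_of(grid, cbind(6:9, 2, 2))
  expect_equal(dice(A, A), 1)
  expect_equal(dice(A, B), 0)
  # |A| = |B| = 100, |A n B| = 50 -> 0.5
  gA <- mask_of(grid, as.matrix(expand.grid(1:10, 1:10, 1)))
  gB <- mask_of(grid, as.matrix(expand.grid(1:10, 1:10, 1)))
  gB$data[, 6:10, 1] <- FALSE
  gB$data[, 1:5, 2] <- TRUE
  expect_equal(sum(gA$data), 100)
  expect_equal(sum(gB$data), 100)
  expect_equal(dice(gA, gB), 0.5)
  # symmetry over random pairs
  set.seed(12)
  for (i in 1:20) {
    X <- vox_mask(array(stats::runif(1000) < 0.3, grid$dim), grid)
    Y <- vox_mask(array(stats::runif(1000) < 0.3, grid$dim), grid)
    expect_identical(dice(X, Y), dice(Y, X))
    expect_true(dice(X, Y) >= 0 && dice(X, Y) <= 1)
  }
  empty <- vox_mask(array(FALSE, grid$dim), grid)
  expect_warning(v <- dice(empty, empty), "NaN")
  expect_true(is.nan(v))
  other <- vox_grid(c(5, 5, 5), 1)
  expect_error(dice(A, vox_mask(array(TRUE, other$dim), other)), "grid")
})

test_that("anatomical accuracy is the inside-reference fraction", {
  grid <- vox_grid(c(10, 10, 10), 1)
  manual <- mask_of(grid, as.matrix(expand.grid(1:5, 1:5, 1:5)))
  inside <- mask_of(grid, as.matrix(expand.grid(2:4, 2:4, 2:4)))
  expect_equal(anatomical_accuracy(inside, manual), 1)
  half <- mask_of(grid, cbind(c(1:4, 6:9), 1, 1))
  expect_equal(anatomical_accuracy(half, manual), 0.5)
  outside <- mask_of(grid, cbind(7:9, 7, 7))
  expect_equal(anatomical_accuracy(outside, manual), 0)
  full <- vox_mask(array(TRUE, grid$dim), grid)
  expect_equal(anatomical_accuracy(inside, full), 1)
  empty <- vox_mask(array(FALSE, grid$dim), grid)
  expect_error(anatomical_accuracy(empty, manual), "empty")
})

test_that("within-subject similarity matches a brute-force set oracle", {
  grid <- vox_grid(c(8, 8, 8), 1)
  set.seed(31)
  test_maps <- list()
  retest_maps <- list()
  oracle <- numeric(3)
  for (i in 1:3) {
    idxA <- unique(cbind(sample(8, 30, TRUE), sample(8, 30, TRUE),
                         sample(8, 30, TRUE)))
    idxB <- unique(cbind(sample(8, 30, TRUE), sample(8, 30, TRUE),
                         sample(8, 30, TRUE)))
    id <- sprintf("s%d", i)
    test_maps[[id]] <- mask_of(grid, idxA)
    retest_maps[[id]] <- mask_of(grid, idxB)
    oracle[i] <- brute_force_dice(idxA, idxB)
  }
  expect_equal(within_subject(test_maps, retest_maps), mean(oracle))
  # identical maps give exactly 1; single subject equals its own DSC
  expect_equal(within_subject(test_maps, test_maps), 1)
  expect_equal(within_subject(test_maps[1], retest_maps[1]), oracle[1])
  expect_error(within_subject(test_maps, retest_maps[c(2, 3, 1)][1:2]),
               "pair")
})

test_that("between-subject similarity averages all unordered pairs", {
  grid <- vox_grid(c(8, 8, 8), 1)
  set.seed(5)
  idx <- lapply(1:3, function(i)
    unique(cbind(sample(8, 40, TRUE), sample(8, 40, TRUE),
                 sample(8, 40, TRUE))))
  maps <- lapply(idx, mask_of, grid = grid)
  oracle <- mean(c(brute_force_dice(idx[[1]], idx[[2]]),
                   brute_force_dice(idx[[1]], idx[[3]]),
                   brute_force_dice(idx[[2]], idx[[3]])))
  expect_equal(between_subject(maps), oracle)
  expect_equal(between_subject(rep(maps[1], 4)), 1)
  disjoint <- list(mask_of(grid, cbind(1:3, 1, 1)),
                   mask_of(grid, cbind(1:3, 3, 3)),
                   mask_of(grid, cbind(1:3, 5, 5)))
  expect_equal(between_subject(disjoint), 0)
  # adding a disjoint map strictly decreases similarity
  expect_lt(between_subject(c(rep(maps[1], 3), disjoint[1])),
            between_subject(rep(maps[1], 3)))
  expect_error(between_subject(maps[1]), "at least 2")
})

test_that("overall score averages hemispheres then the three measures", {
  cfg <- track_config("deterministic", 0.5, 45)
  sc <- overall_score("t", cfg, anatomical_accuracy = c(0.2, 0.2),
                      within_subject = c(0.5, 0.5),
                      between_subject = c(0.8, 0.8))
  expect_equal(sc$overall, 0.5)
  expect_equal(sc$overall,
               mean(c(sc$anatomical_accuracy, sc$within_subject,
                      sc$between_subject)), tolerance = 1e-12)
  # asymmetric hemispheres average per measure first
  sc2 <- overall_score("t", cfg, c(0.2, 0.4), c(0.5, 0.7), c(0.8, 1.0))
  expect_equal(sc2$anatomical_accuracy, 0.3)
  expect_equal(sc2$overall, mean(c(0.3, 0.6, 0.9)))
  # single-hemisphere phantom: the hemisphere mean is that hemisphere's value
  sc3 <- overall_score("t", cfg, 0.25, 0.5, 0.75)
  expect_equal(sc3$overall, 0.5)
  expect_error(overall_score("t", cfg, numeric(0), 0.5, 0.5), "measure")
})
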