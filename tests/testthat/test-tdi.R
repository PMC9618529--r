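test_that("a single straight streamline counts each traversed voxel once", {
  grid <- vox_grid(c(12, 12, 12), 1)
  s <- cbind(5.5, 5.5, seq(2, 9, by = 0.5))
  tg <- tractopt:::new_tractogram(list(s), track_config(step_size = 0.5))
  m <- count_map(tg, grid, upsample_factor = 4L)
  expect_true(all(m$values %in% c(0L, 1L)))
  expect_equal(sum(m$values), sum(m$values > 0))
  # N copies scale linearly
  tgN <- tractopt:::new_tractogram(rep(list(s), 7),
                                   track_config(step_size = 0.5))
  mN <- count_map(tgN, grid, upsample_factor = 4L)
  expect_equal(mN$values, m$values * 7L)
})

test_that("count maps equal the brute-force voxel-visit oracle", {
  grid <- vox_grid(c(16, 16, 16), 1)
  set.seed(99)
  streams <- replicate(120, random_streamline(grid), simplify = FALSE)
  tg <- tractopt:::new_tractogram(streams, track_config(step_size = 0.8))
  for (fac in c(1L, 4L)) {
    m <- count_map(tg, grid, upsample_factor = fac, resolution = 0.01)
    oracle <- brute_force_count_map(streams, grid, factor = fac, res = 0.01)
    expect_equal(sum(m$values), sum(oracle))
    expect_equal(array(as.numeric(m$values), dim(oracle)), oracle)
    # the default quarter-voxel resampling agrees closely (it can only
    # disagree on voxels the path merely corner-clips)
    md <- count_map(tg, grid, upsample_factor = fac)
    expect_gt(sum(md$values) / sum(m$values), 0.9)
    expect_lte(sum(md$values) / sum(m$values), 1.001)
  }
})

test_that("count totals are invariant to streamline reversal", {
  grid <- vox_grid(c(16, 16, 16), 1)
  set.seed(7)
  streams <- replicate(25, random_streamline(grid), simplify = FALSE)
  rev_streams <- lapply(streams, function(s) s[nrow(s):1, , drop = FALSE])
  cfg <- track_config(step_size = 0.8)
  m1 <- count_map(tractopt:::new_tractogram(streams, cfg), grid, 2L)
  m2 <- count_map(tractopt:::new_tractogram(rev_streams, cfg), grid, 2L)
  expect_equal(sum(m1$values), sum(m2$values))
})

test_that("dec maps encode axis-aligned and diagonal directions", {
  grid <- vox_grid(c(12, 12, 12), 1)
  cfg <- track_config(step_size = 0.5)
  rgb_at_traversed <- function(m) {
    hit <- which(apply(m$values != 0, 1:3, any), arr.ind = TRUE)
    expect_gt(nrow(hit), 0)
    t(apply(hit, 1, function(v) m$values[v[1], v[2], v[3], ]))
  }
  sz <- cbind(5.5, 5.5, seq(2, 9, 0.5))
  mz <- dec_map(tractopt:::new_tractogram(list(sz), cfg), grid, 1L)
  for (row in seq_len(nrow(rgb_at_traversed(mz))))
    expect_equal(rgb_at_traversed(mz)[row, ], c(0, 0, 1))
  sx <- cbind(seq(2, 9, 0.5), 5.5, 5.5)
  mx <- dec_map(tractopt:::new_tractogram(list(sx), cfg), grid, 1L)
  expect_true(all(abs(sweep(rgb_at_traversed(mx), 2, c(1, 0, 0))) < 1e-9))
  t45 <- seq(2, 8, 0.5)
  sxy <- cbind(t45, t45, 5.5)
  mxy <- dec_map(tractopt:::new_tractogram(list(sxy), cfg), grid, 1L)
  expect_true(all(abs(sweep(rgb_at_traversed(mxy), 2,
                            c(sqrt(2) / 2, sqrt(2) / 2, 0))) < 1e-9))
  expect_true(all(mxy$values >= 0 & mxy$values <= 1))
})

test_that("afd weighting scales with amplitude and matches per-point oracle", {
  tf <- straight_tube_field(n = 16, radius = 2, amp = 1)
  cfg <- track_config("deterministic", 0.5, 45)
  # hand-made streamlines fully inside the tube (all points at amplitude 1)
  set.seed(3)
  streams <- lapply(1:10, function(i) {
    off <- stats::runif(2, -1, 1)
    cbind(7.5 + off[1], 7.5 + off[2], seq(3, 12, 0.5))
  })
  tg <- tractopt:::new_tractogram(streams, cfg)
  cm <- count_map(tg, tf$grid, 2L)
  am1 <- afd_map(tg, tf$field, tf$grid, 2L)
  expect_equal(am1$values, cm$values * 1.0) # uniform amplitude 1
  half <- tf$field
  half$amps <- half$amps * 0.5
  am05 <- afd_map(tg, half, tf$grid, 2L)
  expect_equal(am05$values, cm$values * 0.5)
  # two-amplitude field (0.2 / 0.8 halves along z): a straight streamline
  # crossing both halves equally carries weight ~0.5
  duo <- tf$field
  d <- tf$grid$dim
  zsplit <- floor(d[3] / 2)
  duo$amps[, , , seq_len(zsplit)] <- duo$amps[, , , seq_len(zsplit)] * 0.2
  duo$amps[, , , (zsplit + 1):d[3]] <- duo$amps[, , , (zsplit + 1):d[3]] * 0.8
  s <- cbind(7.5, 7.5, seq(2, 13, 0.5)) # z centred on the split
  tg1 <- tractopt:::new_tractogram(list(s), cfg)
  w <- tractopt:::afd_weights(tg1, duo)
  # independent per-point oracle
  amp_at <- function(p) {
    v <- grid_voxel(tf$grid, rbind(p))
    if (!in_grid(tf$grid, v)) return(0)
    duo$amps[1, v[1], v[2], v[3]]
  }
  w_oracle <- mean(apply(s, 1, amp_at))
  expect_equal(w, w_oracle, tolerance = 1e-12)
  expect_equal(w, 0.5, tolerance = 0.05)
})

test_that("upsample factor below one is rejected", {
  grid <- vox_grid(c(8, 8, 8), 1)
  tg <- tractopt:::new_tractogram(list(cbind(4, 4, 2:6)), track_config())
  expect_error(count_map(tg, grid, 0L), "upsample_factor")
})
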