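# Small phantoms shared across tests.

straight_tube_field <- function(n = 20L, vox = 1, radius = 2, amp = 1,
                                axis = 3) {
  grid <- vox_grid(rep(n, 3), vox)
  ctr <- grid$origin + (grid$dim - 1) / 2 * grid$vox
  lo <- ctr; hi <- ctr
  lo[axis] <- grid$origin[axis] + 3 * vox
  hi[axis] <- grid$origin[axis] + (n - 4) * vox
  b <- bundle_spec("tube", centerline = rbind(lo, hi), tube_radius = radius,
                   amplitude = amp)
  list(grid = grid, bundle = b, field = make_bundle_field(list(b), grid))
}

quarter_arc_bundle <- function(radius = 10, tube_radius = 2, amp = 1) {
  bundle_spec("arc", arc = list(center = c(5, 15, 5), radius = radius,
                                u = c(1, 0, 0), v = c(0, 0, 1),
                                theta = c(0, 90)),
              tube_radius = tube_radius, amplitude = amp)
}

# Cached default phantom (built once per test run).
.test_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- default_phantom()
    ph
  }
})
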