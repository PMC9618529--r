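`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a base seed and labels
#'
#' A small multiplicative hash over the base seed and any number of scalar
#' components (integers or strings), reduced modulo a 31-bit prime so the
#' result is always a valid `set.seed()` argument. Used to give every
#' (configuration, subject, replicate) combination its own independent,
#' reproducible RNG stream.
#'
#' @param base integer base seed.
#' @param ... integers or character labels mixed into the hash.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(base, ...) {
  m <- 2147483629
  h <- as.numeric(base) %% m
  for (x in list(...)) {
    if (is.character(x)) x <- sum(utf8ToInt(paste(x, collapse = ""))) * 131
    for (v in as.numeric(x)) {
      h <- (h * 48271 + (v %% m) + 11) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

vnorm <- function(x) sqrt(sum(x^2))

unit <- function(x) {
  n <- vnorm(x)
  if (n == 0) stop("cannot normalize zero vector")
  x / n
}

# Angle in degrees between two vectors.
angle_deg <- function(a, b) {
  c0 <- sum(unit(a) * unit(b))
  acos(max(-1, min(1, c0))) * 180 / pi
}

# Rotation matrix for angle theta (radians) about unit axis k (Rodrigues).
rotation_about <- function(k, theta) {
  k <- unit(k)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Small random rotation with axis uniform on the sphere and angle |N(0, sd)|.
random_rotation <- function(sd_deg) {
  if (sd_deg <= 0) return(diag(3))
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  axis <- c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  rotation_about(axis, stats::rnorm(1, 0, sd_deg * pi / 180))
}

to_logical_vec <- function(mask) as.logical(mask$data)

# Streamline arc length (equal-step polyline).
streamline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                      pts[-nrow(pts), , drop = FALSE])^2)))
}
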