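#' Internal helpers: rotations, seeded RNG management, small utilities.
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Uniform random rotation matrix
#'
#' Draws a rotation uniformly from SO(3) via a normalized Gaussian quaternion.
#'
#' @return A 3x3 orthonormal rotation matrix.
#' @keywords internal
#' @noRd
rand_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Rotation about an arbitrary axis (Rodrigues)
#' @noRd
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Derive a child seed from a master seed
#'
#' Documented splitting rule used for per-replica and per-run generators:
#' a multiplicative-congruential step keyed by the child index, kept below
#' 2^31 - 1 so the result is a valid R integer seed.
#'
#' @param master integer master seed.
#' @param k non-negative child index.
#' @return An integer seed.
#' @export
sub_seed <- function(master, k) {
  m <- 2147483647
  s <- (as.numeric(master) %% m)
  as.integer((s * 48271 + as.numeric(k) * 7919 + 12345) %% m)
}

#' Evaluate an expression with a temporary RNG seed
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Squared Euclidean row distances between a point and matrix rows
#' @noRd
row_dist <- function(m, p) {
  sqrt((m[, 1] - p[1])^2 + (m[, 2] - p[2])^2 + (m[, 3] - p[3])^2)
}
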