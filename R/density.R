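#' Voxel density map
#'
#' A minimal in-memory voxel grid: a 3D array of non-negative values, a cubic
#' voxel edge length (A) and the coordinate of the center of voxel
#' \code{[1,1,1]}.
#'
#' @param data 3D numeric array.
#' @param voxel voxel edge length in Angstrom.
#' @param origin length-3 numeric, center of the first voxel.
#' @return A \code{density_map} object.
#' @export
density_map <- function(data, voxel, origin = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3, voxel > 0, length(origin) == 3)
  structure(list(data = data, voxel = voxel, origin = as.numeric(origin)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("<density_map> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", x$voxel, " A, mass ", signif(map_mass(x), 4), "\n", sep = "")
  invisible(x)
}

#' Total map mass (sum of values times voxel volume)
#' @param map a \code{density_map}.
#' @export
map_mass <- function(map) sum(map$data) * map$voxel^3

#' Coordinates of all voxel centers
#' @param map a \code{density_map}.
#' @return n_voxels x 3 matrix, in array (column-major) order.
#' @export
voxel_centers <- function(map) {
  d <- dim(map$data)
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  cbind(x = map$origin[1] + (g$i - 1) * map$voxel,
        y = map$origin[2] + (g$j - 1) * map$voxel,
        z = map$origin[3] + (g$k - 1) * map$voxel)
}

# ---- MRC/CCP4 I/O -----------------------------------------------------------
# Minimal MRC2014 mode-2 (float32) reader/writer. Axis order is kept at
# mapc/mapr/maps = 1/2/3 and the density origin is stored in the ORIGIN words.

#' Write a density map as MRC
#'
#' @param map a \code{\link{density_map}}.
#' @param path output file.
#' @export
write_mrc <- function(map, path) {
  d <- dim(map$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                # nx ny nz
  wi(2)                                # mode 2 = float32
  wi(c(0, 0, 0))                       # nxstart nystart nzstart
  wi(d)                                # mx my mz
  wf(d * map$voxel)                    # cella
  wf(c(90, 90, 90))                    # cellb
  wi(c(1, 2, 3))                       # mapc mapr maps
  v <- range(map$data)
  wf(c(v[1], v[2], mean(map$data)))    # dmin dmax dmean
  wi(1)                                # ispg
  wi(0)                                # nsymbt
  wi(rep(0, 25))                       # extra (incl. exttyp/nversion unset)
  # words 50-52: origin (A); the half-voxel shift keeps voxel centers at
  # origin + index * voxel, matching this package's convention
  wf(map$origin)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(sd(as.numeric(map$data)))         # rms
  wi(0)                                # nlabl
  writeBin(raw(800), con)              # labels
  wf(as.numeric(map$data))             # column-major == x fastest
  invisible(path)
}

#' Read an MRC density map
#'
#' Supports the subset written by \code{\link{write_mrc}} (mode 2, axis order
#' 1/2/3, cubic voxels).
#'
#' @param path MRC file path.
#' @return A \code{\link{density_map}}.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("unsupported MRC mode ", mode, " (only mode 2)")
  ri(3)                 # nstart
  m <- ri(3)            # mx my mz
  cella <- rf(3)
  rf(3)                 # cellb
  axes <- ri(3)
  if (!identical(axes, c(1L, 2L, 3L))) stop("unsupported MRC axis order")
  rf(3)                 # dmin dmax dmean
  ri(2)                 # ispg nsymbt
  ri(25)                # extra
  origin <- rf(3)
  seek(con, 1024)
  vals <- rf(prod(d))
  voxel <- cella[1] / m[1]
  density_map(array(vals, dim = d), voxel = voxel, origin = origin)
}

# ---- Gaussian mixtures ------------------------------------------------------

#' Gaussian mixture density
#'
#' An isotropic Gaussian mixture approximating a density map layer: one row
#' per component (weight, mean, sigma). Weights sum to 1; the map mass is kept
#' as an attribute so total mixture mass stays proportional to map mass.
#'
#' @param weight,x,y,z,sigma equal-length numeric vectors.
#' @param mass total mass represented (default 1).
#' @param source identifier (map + layer label).
#' @export
gaussian_mixture <- function(weight, x, y, z, sigma, mass = 1, source = NULL) {
  stopifnot(all(weight > 0), all(sigma > 0))
  comp <- data.frame(weight = weight / sum(weight), x = x, y = y, z = z,
                     sigma = sigma)
  structure(list(components = comp, mass = mass, source = source),
            class = "gaussian_mixture")
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat("<gaussian_mixture> K =", nrow(x$components), " mass =",
      signif(x$mass, 4), "\n")
  invisible(x)
}

#' Fit an isotropic Gaussian mixture to a density map
#'
#' Weighted expectation-maximization over voxel centers with weights equal to
#' voxel density. Components are isotropic; sigmas are floored at half a voxel
#' to avoid collapse. Initialization is a density-weighted k-means++ style
#' seeding followed by weighted EM, deterministic for a given seed.
#'
#' @param map a \code{\link{density_map}} with non-negative values.
#' @param K number of components (>= 1).
#' @param seed integer seed for the initialization.
#' @param max_iter,tol EM iteration controls.
#' @return A \code{\link{gaussian_mixture}} whose \code{mass} equals the map
#'   mass.
#' @export
fit_gmm_to_map <- function(map, K, seed = 1, max_iter = 200, tol = 1e-8) {
  stopifnot(K >= 1)
  if (any(map$data < 0)) stop("map must be non-negative")
  w <- as.numeric(map$data)
  if (sum(w) == 0) stop("cannot fit a mixture to an all-zero map")
  keep <- w > 0
  X <- voxel_centers(map)[keep, , drop = FALSE]
  w <- w[keep]
  w <- w / sum(w)
  n <- nrow(X)
  K <- min(K, n)
  sig_floor <- map$voxel / 2
  with_seed(seed, {
    # k-means++ style seeding with density weights
    mu <- matrix(0, K, 3)
    mu[1, ] <- X[sample.int(n, 1, prob = w), ]
    if (K > 1) for (k in 2:K) {
      d2 <- Reduce(pmin, lapply(seq_len(k - 1), function(j) {
        (X[, 1] - mu[j, 1])^2 + (X[, 2] - mu[j, 2])^2 + (X[, 3] - mu[j, 3])^2
      }))
      p <- w * d2
      if (sum(p) == 0) p <- w
      mu[k, ] <- X[sample.int(n, 1, prob = p), ]
    }
    pi_k <- rep(1 / K, K)
    sg <- rep(max(map$voxel, sd(row_dist(X, colMeans(X))) / K^(1 / 3)), K)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      # E step: responsibilities (n x K), guarded against underflow
      logd <- vapply(seq_len(K), function(k) {
        d2 <- (X[, 1] - mu[k, 1])^2 + (X[, 2] - mu[k, 2])^2 +
          (X[, 3] - mu[k, 3])^2
        log(pi_k[k]) - 1.5 * log(2 * pi * sg[k]^2) - d2 / (2 * sg[k]^2)
      }, numeric(n))
      mx <- apply(logd, 1, max)
      r <- exp(logd - mx)
      rs <- rowSums(r)
      r <- r / rs
      ll <- sum(w * (mx + log(rs)))
      # M step with voxel weights
      for (k in seq_len(K)) {
        rk <- r[, k] * w
        tot <- sum(rk)
        if (tot < 1e-12) next
        mu[k, ] <- colSums(X * rk) / tot
        d2 <- (X[, 1] - mu[k, 1])^2 + (X[, 2] - mu[k, 2])^2 +
          (X[, 3] - mu[k, 3])^2
        sg[k] <- max(sqrt(sum(rk * d2) / (3 * tot)), sig_floor)
        pi_k[k] <- tot
      }
      pi_k <- pi_k / sum(pi_k)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
      ll_old <- ll
    }
  })
  gaussian_mixture(pi_k, mu[, 1], mu[, 2], mu[, 3], sg,
                   mass = map_mass(map), source = map$source %||% NULL)
}

#' Overlap integral of two isotropic Gaussians
#'
#' \deqn{\int g_1 g_2 = (2\pi(\sigma_1^2+\sigma_2^2))^{-3/2}
#'   \exp(-|\mu_1-\mu_2|^2 / (2(\sigma_1^2+\sigma_2^2)))}
#' for unit-mass normalized 3D Gaussians.
#'
#' @param mu1,mu2 length-3 centers.
#' @param s1,s2 isotropic sigmas.
#' @return The overlap integral (scalar).
#' @export
gaussian_overlap <- function(mu1, s1, mu2, s2) {
  v <- s1^2 + s2^2
  d2 <- sum((mu1 - mu2)^2)
  (2 * pi * v)^(-1.5) * exp(-d2 / (2 * v))
}

#' Overlap matrix between two sets of isotropic Gaussians
#' @param mu_a n x 3 matrix, @param s_a length-n sigmas (recycled), ditto b.
#' @return n_a x n_b matrix of pairwise overlap integrals.
#' @noRd
overlap_matrix <- function(mu_a, s_a, mu_b, s_b) {
  na <- nrow(mu_a); nb <- nrow(mu_b)
  s_a <- rep_len(s_a, na); s_b <- rep_len(s_b, nb)
  d2 <- outer(rowSums(mu_a^2), rowSums(mu_b^2), "+") -
    2 * mu_a %*% t(mu_b)
  v <- outer(s_a^2, s_b^2, "+")
  (2 * pi * v)^(-1.5) * exp(-pmax(d2, 0) / (2 * v))
}
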