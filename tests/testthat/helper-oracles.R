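# Independent brute-force oracles. These re-derive every score from the
# definitions with plain double loops in R, sharing no code with the
# package's kernels.

oracle_ev <- function(coords, radii, pair_i, pair_j, k = 1) {
  s <- 0
  for (p in seq_along(pair_i)) {
    i <- pair_i[p]; j <- pair_j[p]
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    o <- radii[i] + radii[j] - d
    if (o > 0) s <- s + k * o^2
  }
  s
}

oracle_conn <- function(coords, pair_i, pair_j, thr, k = 1) {
  s <- 0
  for (p in seq_along(pair_i)) {
    d <- sqrt(sum((coords[pair_i[p], ] - coords[pair_j[p], ])^2))
    if (d > thr[p]) s <- s + k * (d - thr[p])^2
  }
  s
}

oracle_cyl <- function(coords, idx, radius, k = 1) {
  s <- 0
  for (i in idx) {
    rho <- sqrt(coords[i, 1]^2 + coords[i, 2]^2)
    if (rho > radius) s <- s + k * (rho - radius)^2
  }
  s
}

oracle_overlap <- function(mu1, s1, mu2, s2) {
  v <- s1^2 + s2^2
  (2 * pi * v)^(-1.5) * exp(-sum((mu1 - mu2)^2) / (2 * v))
}

# grid quadrature of the product of two unit-mass isotropic Gaussians
oracle_overlap_quadrature <- function(mu1, s1, mu2, s2, n = 64) {
  lo <- pmin(mu1 - 5 * s1, mu2 - 5 * s2)
  hi <- pmax(mu1 + 5 * s1, mu2 + 5 * s2)
  gs <- lapply(1:3, function(a) seq(lo[a], hi[a], length.out = n))
  h <- vapply(gs, function(g) g[2] - g[1], numeric(1))
  g1 <- lapply(1:3, function(a) exp(-(gs[[a]] - mu1[a])^2 / (2 * s1^2)))
  g2 <- lapply(1:3, function(a) exp(-(gs[[a]] - mu2[a])^2 / (2 * s2^2)))
  c1 <- (2 * pi * s1^2)^(-1.5)
  c2 <- (2 * pi * s2^2)^(-1.5)
  # separable product integral
  c1 * c2 * prod(h) * prod(vapply(1:3, function(a)
    sum(g1[[a]] * g2[[a]]), numeric(1)))
}

oracle_em <- function(coords, radii, idx, bw, mu, ds, dw, sigma_em) {
  K <- nrow(mu)
  ovdd <- numeric(K)
  for (k in seq_len(K)) for (j in seq_len(K))
    ovdd[k] <- ovdd[k] + dw[j] * oracle_overlap(mu[j, ], ds[j], mu[k, ], ds[k])
  s <- 0
  for (k in seq_len(K)) {
    ovmd <- 0
    for (p in seq_along(idx))
      ovmd <- ovmd + bw[p] * oracle_overlap(coords[idx[p], ], radii[idx[p]],
                                            mu[k, ], ds[k])
    s <- s + 0.5 * log(ovmd / ovdd[k])^2 / sigma_em^2
  }
  s
}

oracle_min_surface <- function(coords, radii, ia, ib) {
  best <- Inf
  for (i in ia) for (j in ib) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2)) - radii[i] - radii[j]
    if (d < best) best <- d
  }
  best
}

oracle_binding <- function(coords, radii, a_by_copy, b_by_copy, a_all, b_all,
                           w = 1, k = 1) {
  s <- 0
  for (ix in a_by_copy) {
    d <- oracle_min_surface(coords, radii, ix, b_all)
    if (d > 0) s <- s + w * k * d^2
  }
  for (ix in b_by_copy) {
    d <- oracle_min_surface(coords, radii, ix, a_all)
    if (d > 0) s <- s + w * k * d^2
  }
  s
}

oracle_immuno <- function(coords, copy_idx, mean_d, sem) {
  s <- 0
  for (ix in copy_idx) {
    z <- coords[ix, 3]
    zbest <- z[which.min(abs(z - mean_d))]
    s <- s + 0.5 * ((zbest - mean_d) / sem)^2
  }
  s
}

# full-term oracle for a compiled plan
oracle_terms <- function(plan, coords) {
  s <- c(em = 0, immuno_em = 0, binding = 0, cylinder = 0,
         excluded_volume = 0, connectivity = 0)
  if (!is.null(plan$ev))
    s["excluded_volume"] <- oracle_ev(coords, plan$radii, plan$ev$i,
                                      plan$ev$j, plan$ev$k)
  if (!is.null(plan$conn))
    s["connectivity"] <- plan$conn$constant +
      oracle_conn(coords, plan$conn$i, plan$conn$j, plan$conn$thr, plan$conn$k)
  if (!is.null(plan$cyl))
    s["cylinder"] <- oracle_cyl(coords, plan$cyl$idx, plan$cyl$radius,
                                plan$cyl$k)
  if (!is.null(plan$em))
    s["em"] <- sum(vapply(plan$em, function(e)
      oracle_em(coords, plan$radii, e$idx, e$bw, e$mu, e$ds, e$dw,
                e$sigma_em), numeric(1)))
  if (!is.null(plan$immuno))
    s["immuno_em"] <- sum(vapply(plan$immuno, function(r)
      oracle_immuno(coords, r$copy_idx, r$mean_d, r$sem), numeric(1)))
  if (!is.null(plan$binding))
    s["binding"] <- sum(vapply(plan$binding, function(r)
      oracle_binding(coords, plan$radii, r$a_by_copy, r$b_by_copy,
                     r$a_all, r$b_all, r$w, r$k), numeric(1)))
  s
}

# exhaustive copy-pairing RMSD (enumerates every permutation per protein)
oracle_perm_rmsd <- function(ca, cb, grouping) {
  perms <- function(n) {
    if (n == 1) return(matrix(1))
    p <- perms(n - 1)
    do.call(rbind, lapply(seq_len(n), function(k)
      cbind(k, ifelse(p >= k, p + 1, p))))
  }
  ssd <- 0; nb <- 0
  for (g in grouping) {
    nc <- ncol(g$idx)
    nb <- nb + nc * nrow(g$idx)
    if (!g$interchangeable || nc == 1) {
      for (cp in seq_len(nc))
        ssd <- ssd + sum((ca[g$idx[, cp], ] - cb[g$idx[, cp], ])^2)
    } else {
      best <- Inf
      for (r in seq_len(nrow(perms(nc)))) {
        pm <- perms(nc)[r, ]
        tot <- 0
        for (cp in seq_len(nc))
          tot <- tot + sum((ca[g$idx[, cp], ] - cb[g$idx[, pm[cp]], ])^2)
        best <- min(best, tot)
      }
      ssd <- ssd + best
    }
  }
  sqrt(ssd / nb)
}
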