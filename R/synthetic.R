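#' Toy assembly specification
#'
#' Parameters of the default synthetic two-layer cylindrical assembly:
#' three proteins, two copies each, about 30 beads total, confined to a
#' 60 A radius cylinder with two 40 A z-bands. The cast emulates the layered
#' plaque architecture: \code{arm} has a structured armadillo-like core in
#' the membrane-proximal layer (A) plus a flexible tail penetrating the upper
#' layer (B); \code{plak} has a structured core restrained by the upper-layer
#' density plus a flexible outward tail; \code{anc} is a membrane-anchored
#' flexible cadherin-like chain threading both layers and touching both
#' structured cores.
#'
#' @param cyl_radius confinement cylinder radius (A).
#' @param layer_a,layer_b z-bands of the two layers (A).
#' @param sem immuno-EM standard error (A).
#' @return A parameter list consumed by \code{\link{generate_toy_assembly}}.
#' @export
toy_spec <- function(cyl_radius = 60, layer_a = c(0, 40), layer_b = c(40, 80),
                     sem = 5) {
  list(cyl_radius = cyl_radius, layer_a = layer_a, layer_b = layer_b,
       sem = sem,
       r_arm = 30, col_sep = 32,
       arm_core_z = c(16, 30), plak_core_z = c(54, 66, 78))
}

#' Synthetic residue coordinates for a rigid domain
#'
#' Residues of each segment sit on a small ring around the segment center;
#' segment centers stack vertically, so bead centers are exactly the segment
#' centers. Deterministic.
#' @noRd
synthetic_domain_coords <- function(n_res, rpb, spacing) {
  nseg <- ceiling(n_res / rpb)
  out <- lapply(seq_len(nseg), function(s) {
    lo <- (s - 1) * rpb + 1
    hi <- min(s * rpb, n_res)
    k <- hi - lo + 1
    ang <- 2 * pi * (seq_len(k) - 1) / k
    data.frame(resno = lo:hi, x = 3 * cos(ang), y = 3 * sin(ang),
               z = (s - 1) * spacing)
  })
  do.call(rbind, out)
}

#' Default toy topology
#'
#' @param spec a \code{\link{toy_spec}} parameter list.
#' @return An \code{\link{assembly_topology}} (3 proteins x 2 copies,
#'   30 beads).
#' @export
toy_topology <- function(spec = toy_spec()) {
  aa <- function(n) paste(rep_len(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n),
                          collapse = "")
  arm_src <- synthetic_domain_coords(60, 30, diff(spec$arm_core_z))
  plak_src <- synthetic_domain_coords(90, 30, diff(spec$plak_core_z)[1])
  assembly_topology(list(
    protein_spec("anc", aa(120), copies = 2, disorder_fraction = 0.4,
                 domains = list(
                   domain_spec("tail", c(1, 120), "flexible", anchored = TRUE))),
    protein_spec("arm", aa(100), copies = 2, disorder_fraction = 0.5,
                 domains = list(
                   domain_spec("core", c(1, 60), "rigid",
                               structure_source = arm_src,
                               em_restrained = TRUE, layer = "A"),
                   domain_spec("tail", c(61, 100), "flexible"))),
    protein_spec("plak", aa(130), copies = 2, disorder_fraction = 0.4,
                 domains = list(
                   domain_spec("core", c(1, 90), "rigid",
                               structure_source = plak_src,
                               em_restrained = TRUE, layer = "B"),
                   domain_spec("tail", c(91, 130), "flexible")))
  ))
}

#' Place a point tangent to a sphere
#' @noRd
tangent_point <- function(center, r_center, r_bead, dir) {
  u <- dir / sqrt(sum(dir^2))
  center + (r_center + r_bead) * u
}

#' Generate a toy layered assembly with planted ground truth
#'
#' Constructs a ground-truth configuration that satisfies all its own
#' restraints: structured cores posed inside their layer z-bands, flexible
#' chains threaded with every consecutive gap below the connectivity
#' threshold, anchored beads exactly on the membrane plane, no
#' excluded-volume violation, and four planted inter-protein domain contacts
#' realized as exact surface tangencies (anc-arm core, anc-plak core,
#' anc-arm tail, arm tail-plak core). Construction is randomized (azimuths,
#' spins, waypoint jitter) and verified; failing draws are retried.
#'
#' @param spec a \code{\link{toy_spec}}.
#' @param seed integer seed.
#' @param max_tries attempts before giving up.
#' @return A \code{toy_ground_truth}: list(topology, rep, coords, contacts,
#'   spec, seed).
#' @export
generate_toy_assembly <- function(spec = toy_spec(), seed = 1,
                                  max_tries = 200) {
  topo <- toy_topology(spec)
  rep_ <- build_representation(topo)
  for (attempt in seq_len(max_tries)) {
    coords <- with_seed(sub_seed(seed, attempt),
                        try(place_toy_truth(rep_, spec), silent = TRUE))
    if (inherits(coords, "try-error")) next
    if (verify_toy_truth(rep_, coords, spec)) {
      contacts <- enumerate_contacts(rep_, coords)
      return(structure(list(topology = topo, rep = rep_, coords = coords,
                            contacts = contacts, spec = spec, seed = seed),
                       class = "toy_ground_truth"))
    }
  }
  stop("could not construct a valid toy ground truth in ", max_tries,
       " attempts")
}

#' @export
print.toy_ground_truth <- function(x, ...) {
  cat("<toy_ground_truth> ", nrow(x$rep$beads), " beads, ",
      nrow(x$contacts), " planted contacts\n", sep = "")
  invisible(x)
}

#' One randomized construction attempt (may violate constraints; verified by
#' the caller)
#' @noRd
place_toy_truth <- function(rep_, spec) {
  b <- rep_$beads
  coords <- rep_$coords
  phi0 <- runif(1, 0, 2 * pi)
  bead_at <- function(protein, cp, domain, slot)
    which(b$protein == protein & b$copy == cp & b$domain == domain &
            b$slot == slot)
  jxy <- function() runif(2, -0.5, 0.5)
  jdir <- function(u) u + runif(3, -0.03, 0.03)
  pose_body <- function(idx, center, spin) {
    local <- sweep(rep_$coords[idx, , drop = FALSE], 2,
                   colMeans(rep_$coords[idx, , drop = FALSE]))
    R <- rotation_about_axis(c(0, 0, 1), spin)
    sweep(local %*% t(R), 2, center, "+")
  }
  for (cp in 1:2) {
    phi <- phi0 + pi * (cp - 1) + runif(1, -0.1, 0.1)
    e_r <- c(cos(phi), sin(phi), 0)
    e_t <- c(-sin(phi), cos(phi), 0)
    # local column frame: a_hat points from the arm column to the plak
    # column (inward-tangential), b_hat is the perpendicular flank direction
    a_hat <- -0.55 * e_r + 0.835 * e_t
    a_hat <- a_hat / sqrt(sum(a_hat^2))
    b_hat <- 0.835 * e_r + 0.55 * e_t
    b_hat <- b_hat / sqrt(sum(b_hat^2))
    arm_xy <- spec$r_arm * e_r
    at <- function(a, bb, z) arm_xy + a * a_hat + bb * b_hat + c(0, 0, z)
    i_armc <- which(b$protein == "arm" & b$copy == cp & b$domain == "core")
    coords[i_armc, ] <- pose_body(i_armc, at(0, 0, mean(spec$arm_core_z)),
                                  runif(1, 0, 2 * pi))
    i_plakc <- which(b$protein == "plak" & b$copy == cp & b$domain == "core")
    coords[i_plakc, ] <- pose_body(i_plakc,
                                   at(spec$col_sep, 0, mean(spec$plak_core_z)),
                                   runif(1, 0, 2 * pi))
    armb1 <- coords[bead_at("arm", cp, "core", 1), ]
    plakb1 <- coords[bead_at("plak", cp, "core", 1), ]
    plakb2 <- coords[bead_at("plak", cp, "core", 2), ]
    plakb3 <- coords[bead_at("plak", cp, "core", 3), ]
    r20 <- bead_radius(20); r30 <- bead_radius(30)
    ia <- vapply(1:6, function(s) bead_at("anc", cp, "tail", s), integer(1))
    it <- vapply(1:2, function(s) bead_at("arm", cp, "tail", s), integer(1))
    ip <- vapply(1:2, function(s) bead_at("plak", cp, "tail", s), integer(1))
    # anchored chain climbs the minus-b flank: bead 2 tangent to the lower
    # arm-core bead from below, bead 6 tangent to the lowest plak-core bead
    coords[ia[2], ] <- tangent_point(armb1, r30, r20,
                                     jdir(c(0.5 * a_hat[1:2] -
                                              0.62 * b_hat[1:2], -0.6)))
    coords[ia[1], ] <- c(coords[ia[2], 1:2], 0)
    coords[ia[6], ] <- tangent_point(plakb1, r30, r20,
                                     jdir(c(-0.35 * a_hat[1:2] -
                                              0.7 * b_hat[1:2], -0.62)))
    coords[ia[3], ] <- at(14.5, -14.5, 17) + c(jxy(), runif(1, -0.5, 0.5))
    coords[ia[4], ] <- at(17.5, -14.5, 25) + c(jxy(), runif(1, -0.5, 0.5))
    coords[ia[5], ] <- at(22.5, -15, 34.5) + c(jxy(), runif(1, -0.5, 0.5))
    # short arm tail on the plus-b flank: bead 1 tangent to anc bead 4
    # (planted anc / arm-tail contact), bead 2 tangent to the lowest
    # plak-core bead (planted arm-tail / plak-core contact)
    coords[it[1], ] <- tangent_point(coords[ia[4], ], r20, r20,
                                     jdir(c(-0.39 * a_hat[1:2] +
                                              0.79 * b_hat[1:2], 0.47)))
    coords[it[2], ] <- tangent_point(plakb1, r30, r20,
                                     jdir(c(-0.65 * a_hat[1:2] +
                                              0.2 * b_hat[1:2], -0.73)))
    # plak tail walks up and outward from the top core bead
    u_p <- c(0.7 * e_r[1:2], 0.714)
    coords[ip[1], ] <- plakb3 + 14 * u_p + c(jxy(), 0)
    coords[ip[2], ] <- coords[ip[1], ] + 13 * u_p + c(jxy(), 0)
  }
  coords
}

#' Verify a constructed ground truth against its own constraints
#' @noRd
verify_toy_truth <- function(rep_, coords, spec, tol = 1e-9) {
  b <- rep_$beads
  if (any(!is.finite(coords))) return(FALSE)
  if (any(coords[, 3] < -tol)) return(FALSE)
  if (any(sqrt(coords[, 1]^2 + coords[, 2]^2) > spec$cyl_radius))
    return(FALSE)
  cp <- consecutive_pairs(rep_)
  gaps <- sqrt(rowSums((coords[cp$i, ] - coords[cp$j, ])^2))
  if (any(!cp$intra_body & gaps > 0.98 * cp$threshold)) return(FALSE)
  # excluded volume (exempting intra-body and consecutive pairs)
  pr <- t(combn(nrow(b), 2))
  same_body <- !is.na(b$rigid_body[pr[, 1]]) & !is.na(b$rigid_body[pr[, 2]]) &
    b$rigid_body[pr[, 1]] == b$rigid_body[pr[, 2]]
  consec <- paste(pr[, 1], pr[, 2]) %in%
    c(paste(cp$i, cp$j), paste(cp$j, cp$i))
  pr <- pr[!(same_body | consec), , drop = FALSE]
  d <- sqrt(rowSums((coords[pr[, 1], ] - coords[pr[, 2], ])^2))
  overlap <- b$radius[pr[, 1]] + b$radius[pr[, 2]] - d
  if (any(overlap > tol)) return(FALSE)
  # structured beads inside their layer bands
  in_band <- function(z, band) z >= band[1] & z <= band[2]
  za <- coords[b$em_restrained & b$layer %in% "A", 3]
  zb <- coords[b$em_restrained & b$layer %in% "B", 3]
  if (!all(in_band(za, spec$layer_a)) || !all(in_band(zb, spec$layer_b)))
    return(FALSE)
  if (any(abs(coords[b$anchored, 3]) > 0)) return(FALSE)
  # the four planted tangencies must exist per copy
  nrow(enumerate_contacts(rep_, coords)) == 4
}

#' Enumerate contacting domain pairs of a configuration
#'
#' Domain pairs of distinct proteins whose minimum surface-to-surface
#' distance (over all copies and beads) is at or below \code{tol}.
#'
#' @param rep_ representation; @param coords coordinate matrix.
#' @param tol touch tolerance (A) for the degenerate exact-tangency case.
#' @return Data frame in the binding-record domain format with the measured
#'   minimum distance.
#' @export
enumerate_contacts <- function(rep_, coords, tol = 1e-6) {
  b <- rep_$beads
  doms <- unique(b[, c("protein", "domain")])
  doms$key <- paste(doms$protein, doms$domain)
  out <- list()
  for (i in seq_len(nrow(doms) - 1)) for (j in (i + 1):nrow(doms)) {
    if (doms$protein[i] == doms$protein[j]) next
    ia <- which(b$protein == doms$protein[i] & b$domain == doms$domain[i])
    ib <- which(b$protein == doms$protein[j] & b$domain == doms$domain[j])
    d <- min_surface_dist_cpp(coords, b$radius, ia, ib)
    if (d <= tol) {
      ra <- range(b$res_start[ia], b$res_end[ia])
      rb <- range(b$res_start[ib], b$res_end[ib])
      out[[length(out) + 1L]] <- data.frame(
        protein_a = doms$protein[i], res_start_a = ra[1], res_end_a = ra[2],
        domain_a = doms$domain[i],
        protein_b = doms$protein[j], res_start_b = rb[1], res_end_b = rb[2],
        domain_b = doms$domain[j], min_distance = d)
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

#' Simulate a segmented density map for one layer
#'
#' Sum of the layer's density-restrained bead Gaussians (sigma = bead radius
#' unless \code{blur_sigma} is given, mass = residue count), rasterized on a
#' cubic grid covering the cylinder and the layer band.
#'
#' @param truth a \code{toy_ground_truth}.
#' @param layer layer label.
#' @param voxel voxel edge (A).
#' @param blur_sigma optional common sigma override.
#' @return A \code{\link{density_map}}.
#' @export
simulate_density_map <- function(truth, layer, voxel = 5, blur_sigma = NULL) {
  b <- truth$rep$beads
  sel <- which(b$em_restrained & b$layer %in% layer)
  if (!length(sel)) stop("no density-restrained beads in layer '", layer, "'")
  band <- if (layer == "A") truth$spec$layer_a else truth$spec$layer_b
  rmax <- max(b$radius[sel])
  lim <- truth$spec$cyl_radius + 2 * rmax
  gx <- seq(-lim, lim, by = voxel)
  gz <- seq(band[1] - 2 * rmax, band[2] + 2 * rmax, by = voxel)
  arr <- array(0, c(length(gx), length(gx), length(gz)))
  for (i in sel) {
    s <- if (is.null(blur_sigma)) b$radius[i] else blur_sigma
    w <- b$n_res[i]
    fx <- exp(-(gx - truth$coords[i, 1])^2 / (2 * s^2))
    fy <- exp(-(gx - truth$coords[i, 2])^2 / (2 * s^2))
    fz <- exp(-(gz - truth$coords[i, 3])^2 / (2 * s^2))
    arr <- arr + w * (2 * pi * s^2)^(-1.5) * outer(outer(fx, fy), fz)
  }
  density_map(arr, voxel, origin = c(-lim, -lim, band[1] - 2 * rmax))
}

#' Simulate an immuno-EM terminus-distance table
#'
#' One record per protein terminus (N and C): antibody-binding range equal to
#' the terminal bead's residues; reported mean = true terminus z (averaged
#' over copies) plus Gaussian noise with standard deviation \code{sem}.
#'
#' @param truth a \code{toy_ground_truth}.
#' @param sem standard error of the mean (A).
#' @param seed integer seed.
#' @return Data frame in the immuno-EM CSV format.
#' @export
simulate_immuno_em <- function(truth, sem = truth$spec$sem, seed = 1) {
  b <- truth$rep$beads
  out <- list()
  with_seed(seed, {
    for (p in truth$topology$proteins) {
      rows <- which(b$protein == p$name & b$copy == 1)
      rows <- rows[order(b$res_start[rows])]
      for (term in c("N", "C")) {
        bead <- if (term == "N") rows[1] else rows[length(rows)]
        sel <- which(b$protein == p$name &
                       b$res_start == b$res_start[bead])
        true_z <- mean(truth$coords[sel, 3])
        out[[length(out) + 1L]] <- data.frame(
          protein = p$name, terminus = term,
          res_start = b$res_start[bead], res_end = b$res_end[bead],
          mean_distance = true_z + rnorm(1) * sem,
          sem = max(sem, 1e-6))
      }
    }
  })
  do.call(rbind, out)
}

#' Simulate a protein-protein binding table
#'
#' One record per contacting domain pair of the ground truth (planted
#' contacts); assay types are drawn from \code{assay_mix}.
#'
#' @param truth a \code{toy_ground_truth}.
#' @param assay_mix assay classes to cycle through.
#' @param seed integer seed.
#' @return Data frame in the binding CSV format.
#' @export
simulate_binding_data <- function(truth,
                                  assay_mix = c("overlay", "coIP", "Y2H"),
                                  seed = 1) {
  cc <- truth$contacts
  if (!nrow(cc)) stop("ground truth has no planted contacts")
  with_seed(seed, {
    cc$assay <- sample(rep_len(assay_mix, nrow(cc)))
  })
  cc[, c("protein_a", "res_start_a", "res_end_a",
         "protein_b", "res_start_b", "res_end_b", "assay")]
}

#' Perturbed ensemble around one or two reference configurations
#'
#' Builds a planted ensemble for analysis-protocol tests: rigid bodies get
#' small random rotations and translations, flexible beads iid Gaussian
#' displacements (anchored beads move in-plane only). With two references,
#' runs are assigned one basin each (a two-basin ensemble split by run).
#'
#' @param truth a \code{toy_ground_truth} (supplies representation + coords).
#' @param n number of frames.
#' @param sd displacement scale (A).
#' @param n_runs number of pseudo-runs in the provenance.
#' @param second_basin optional second reference coordinate matrix; frames of
#'   the upper half of runs are perturbed around it.
#' @param seed integer seed.
#' @return An \code{\link{ensemble}} (scores: synthetic unit-variance totals).
#' @export
perturbed_ensemble <- function(truth, n = 100, sd = 3, n_runs = 2,
                               second_basin = NULL, seed = 1) {
  rep_ <- truth$rep
  b <- rep_$beads
  frames <- vector("list", n)
  runs <- rep(seq_len(n_runs), length.out = n)
  runs <- sort(runs)
  with_seed(seed, {
    for (f in seq_len(n)) {
      base <- truth$coords
      if (!is.null(second_basin) && runs[f] > n_runs / 2) base <- second_basin
      co <- base
      for (body in rep_$rigid_bodies) {
        ctr <- colMeans(co[body, , drop = FALSE])
        R <- rotation_about_axis(rnorm(3) + 1e-6, rnorm(1, 0, sd / 50))
        tr <- rnorm(3, 0, sd)
        co[body, ] <- sweep(sweep(co[body, , drop = FALSE], 2, ctr) %*% t(R),
                            2, ctr + tr, "+")
      }
      flex <- which(b$mobile & is.na(b$rigid_body))
      co[flex, ] <- co[flex, , drop = FALSE] +
        matrix(rnorm(3 * length(flex), 0, sd), ncol = 3)
      anc <- which(b$anchored)
      co[anc, 3] <- base[anc, 3]
      frames[[f]] <- co
    }
    scores <- data.frame(em = 0, immuno_em = 0, binding = 0, cylinder = 0,
                         excluded_volume = 0, connectivity = 0,
                         total = rnorm(n, 100, 1))
  })
  meta <- data.frame(run = runs, replica = 1L, sweep = seq_len(n),
                     temperature = 1)
  ensemble(frames, scores, meta, rep_)
}
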