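#' Fit of cluster models to a binding record
#'
#' Per model, the minimum surface-to-surface distance among all bipartite
#' pairs of beads representing all copies of the two interacting domains.
#'
#' @param ens cluster models (an \code{\link{ensemble}}).
#' @param record one-row data frame in the binding-table format (see
#'   \code{\link{read_binding_csv}}).
#' @param tol touch tolerance (A) for the satisfied fraction, so exact
#'   tangencies are not lost to floating-point noise.
#' @return List: \code{distances} (per frame, A) and \code{satisfied} =
#'   fraction of models with distance <= tol.
#' @export
binding_fit <- function(ens, record, tol = 1e-6) {
  b <- ens$rep$beads
  ia <- which(b$protein == record$protein_a &
                b$res_end >= record$res_start_a &
                b$res_start <= record$res_end_a)
  ib <- which(b$protein == record$protein_b &
                b$res_end >= record$res_start_b &
                b$res_start <= record$res_end_b)
  if (!length(ia) || !length(ib)) stop("record domains not in representation")
  d <- vapply(ens$frames, function(f)
    min_surface_dist_cpp(f, b$radius, ia, ib), numeric(1))
  list(distances = d, satisfied = mean(d <= tol))
}

#' Fit of cluster models to an immuno-EM record
#'
#' Per model and protein copy: difference between the model-predicted
#' terminus distance to the membrane (z of the antibody-range bead closest to
#' the experimental mean) and the experimental mean.
#'
#' @param ens cluster models.
#' @param record one-row immuno-EM data frame (see
#'   \code{\link{read_immuno_em_csv}}).
#' @return Numeric vector of differences (frames x copies).
#' @export
immuno_em_fit <- function(ens, record) {
  b <- ens$rep$beads
  pb <- which(b$protein == record$protein &
                b$res_end >= record$res_start & b$res_start <= record$res_end)
  if (!length(pb)) stop("no bead overlaps the antibody-binding range")
  copies <- sort(unique(b$copy[pb]))
  unlist(lapply(ens$frames, function(f) {
    vapply(copies, function(cp) {
      ix <- pb[b$copy[pb] == cp]
      z <- f[ix, 3]
      z[which.min(abs(z - record$mean_distance))] - record$mean_distance
    }, numeric(1))
  }))
}

#' Cross-correlation between two densities
#'
#' Pearson correlation over voxels of the common grid. If grids differ, the
#' first density is resampled onto the second's grid by trilinear
#' interpolation. Voxels where either density is positive are included;
#' the result is invariant to positive rescaling of either map.
#'
#' @param d1,d2 \code{\link{density_map}} objects.
#' @return Correlation in [-1, 1].
#' @export
density_cross_correlation <- function(d1, d2) {
  same <- identical(dim(d1$data), dim(d2$data)) &&
    isTRUE(all.equal(d1$voxel, d2$voxel)) &&
    isTRUE(all.equal(d1$origin, d2$origin))
  if (!same) d1 <- resample_map(d1, d2)
  a <- as.numeric(d1$data); b <- as.numeric(d2$data)
  keep <- a > 0 | b > 0
  if (sum(keep) < 3 || sd(a[keep]) == 0 || sd(b[keep]) == 0)
    stop("degenerate densities for cross-correlation")
  cor(a[keep], b[keep])
}

#' Trilinear resampling of a map onto a target grid
#' @noRd
resample_map <- function(src, target) {
  tc <- voxel_centers(target)
  g <- (sweep(tc, 2, src$origin)) / src$voxel  # 0-based fractional indices
  d <- dim(src$data)
  i0 <- pmin(pmax(floor(g[, 1]), 0), d[1] - 1); fx <- g[, 1] - i0
  j0 <- pmin(pmax(floor(g[, 2]), 0), d[2] - 1); fy <- g[, 2] - j0
  k0 <- pmin(pmax(floor(g[, 3]), 0), d[3] - 1); fz <- g[, 3] - k0
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1)
  fz <- pmin(pmax(fz, 0), 1)
  val <- numeric(nrow(tc))
  at <- function(i, j, k) {
    ok <- i >= 0 & i < d[1] & j >= 0 & j < d[2] & k >= 0 & k < d[3]
    out <- numeric(length(i))
    out[ok] <- src$data[cbind(i[ok] + 1, j[ok] + 1, k[ok] + 1)]
    out
  }
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) fx else 1 - fx) * (if (dj) fy else 1 - fy) *
      (if (dk) fz else 1 - fz)
    val <- val + w * at(i0 + di, j0 + dj, k0 + dk)
  }
  density_map(array(val, dim(target$data)), target$voxel, target$origin)
}

#' Contact map between two proteins
#'
#' For each bead-slot pair of the two proteins, the proportion of models with
#' at least one contact (surface-to-surface distance <= cutoff) across all
#' copy pairs of the two proteins (any-copy semantics).
#'
#' @param ens cluster models.
#' @param protein_a,protein_b protein names (must differ).
#' @param cutoff contact distance (default 10 A).
#' @return A \code{contact_map}: frequency matrix (slots of A x slots of B)
#'   with bead residue-range metadata.
#' @export
contact_map <- function(ens, protein_a, protein_b, cutoff = 10) {
  stopifnot(protein_a != protein_b)
  b <- ens$rep$beads
  g <- rmsd_grouping(ens$rep)
  ia <- g[[protein_a]]$idx; ib <- g[[protein_b]]$idx
  na <- nrow(ia); nb <- nrow(ib)
  freq <- matrix(0, na, nb)
  ra <- b$radius[ia[, 1]]; rb <- b$radius[ib[, 1]]
  for (f in ens$frames) {
    hit <- matrix(FALSE, na, nb)
    for (ca in seq_len(ncol(ia))) for (cb in seq_len(ncol(ib))) {
      A <- f[ia[, ca], , drop = FALSE]; B <- f[ib[, cb], , drop = FALSE]
      d <- sqrt(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B))
      hit <- hit | (d - outer(ra, rb, "+") <= cutoff)
    }
    freq <- freq + hit
  }
  structure(list(
    frequency = freq / length(ens$frames),
    protein_a = protein_a, protein_b = protein_b, cutoff = cutoff,
    beads_a = b[ia[, 1], c("domain", "slot", "res_start", "res_end")],
    beads_b = b[ib[, 1], c("domain", "slot", "res_start", "res_end")]),
    class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> ", x$protein_a, " x ", x$protein_b, " (",
      nrow(x$frequency), " x ", ncol(x$frequency), " beads, cutoff ",
      x$cutoff, " A)\n", sep = "")
  invisible(x)
}

#' Significant contacts of a contact map
#'
#' Bead pairs whose contact frequency reaches \code{min_frequency}
#' (conventionally 0.20-0.25, filtering out contacts occurring by chance),
#' plus a report of which percentile of all possible pairs the threshold
#' captures.
#'
#' @param map a \code{\link{contact_map}}.
#' @param min_frequency call threshold in [0, 1].
#' @return List: \code{calls} data frame (slot_a, slot_b, domain_a, domain_b,
#'   frequency) sorted by frequency, and \code{top_fraction} = called pairs /
#'   all pairs.
#' @export
significant_contacts <- function(map, min_frequency = 0.25) {
  idx <- which(map$frequency >= min_frequency, arr.ind = TRUE)
  calls <- data.frame(
    slot_a = map$beads_a$slot[idx[, 1]],
    domain_a = map$beads_a$domain[idx[, 1]],
    slot_b = map$beads_b$slot[idx[, 2]],
    domain_b = map$beads_b$domain[idx[, 2]],
    frequency = map$frequency[idx])
  calls <- calls[order(-calls$frequency), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls,
       top_fraction = nrow(calls) / length(map$frequency),
       min_frequency = min_frequency)
}

#' dSTORM plaque-to-plaque to distance-to-membrane transform
#'
#' Converts a plaque-to-plaque distance P measured between mirrored plaques
#' of adjacent cells into a distance from the plasma membrane:
#' \eqn{d = (P - w - 2t)/2} with intercellular width w and membrane thickness
#' t, evaluated at both thickness bounds.
#'
#' @param plaque_to_plaque P in nm.
#' @param intercellular intercellular space width (default 34 nm).
#' @param membrane_thickness length-2 bounds in nm (default c(4, 6)).
#' @return Named vector of distances at the two thickness bounds (nm).
#' @export
dstorm_transform <- function(plaque_to_plaque, intercellular = 34,
                             membrane_thickness = c(4, 6)) {
  d <- (plaque_to_plaque - intercellular - 2 * membrane_thickness) / 2
  setNames(d, paste0("t", membrane_thickness))
}

#' Spacing between the membrane-anchored beads of two cadherins
#'
#' Per model, the minimum center-to-center distance between the anchored
#' beads of the two proteins (a proxy for the spacing of adjacent cadherins
#' at the plasma membrane).
#'
#' @param ens cluster models.
#' @param protein_a,protein_b the two cadherin names.
#' @return Numeric vector (one distance per frame, A).
#' @export
cadherin_spacing <- function(ens, protein_a, protein_b) {
  b <- ens$rep$beads
  ia <- which(b$protein == protein_a & b$anchored)
  ib <- which(b$protein == protein_b & b$anchored)
  if (!length(ia) || !length(ib)) stop("both proteins need anchored beads")
  vapply(ens$frames, function(f) {
    A <- f[ia, , drop = FALSE]; B <- f[ib, , drop = FALSE]
    min(sqrt(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)))
  }, numeric(1))
}

#' Map mutations onto the representation
#'
#' Each residue is mapped to its bead and annotated with the domain, the
#' representation kind, and whether the bead participates in any significant
#' interface call. Residues outside every modeled domain are flagged
#' unmappable, not dropped.
#'
#' @param mutations data frame with columns \code{protein, residue,
#'   substitution, disease}.
#' @param rep an \code{assembly_representation}.
#' @param contacts optional list of \code{\link{significant_contacts}}
#'   results (with their contact maps' protein names), used for interface
#'   membership.
#' @return Annotated data frame.
#' @export
map_mutations <- function(mutations, rep, contacts = NULL) {
  b <- rep$beads
  iface <- list()
  for (sc in contacts %||% list()) {
    for (r in seq_len(nrow(sc$calls))) {
      iface[[length(iface) + 1L]] <-
        data.frame(protein = c(sc$protein_a, sc$protein_b),
                   slot = c(sc$calls$slot_a[r], sc$calls$slot_b[r]),
                   domain = c(sc$calls$domain_a[r], sc$calls$domain_b[r]))
    }
  }
  iface <- if (length(iface)) unique(do.call(rbind, iface)) else NULL
  out <- mutations
  out$domain <- NA_character_; out$kind <- NA_character_
  out$bead_slot <- NA_integer_; out$unmappable <- FALSE
  out$interface <- FALSE
  for (i in seq_len(nrow(mutations))) {
    hit <- which(b$protein == mutations$protein[i] & b$copy == 1 &
                   b$res_start <= mutations$residue[i] &
                   b$res_end >= mutations$residue[i])
    if (!length(hit)) { out$unmappable[i] <- TRUE; next }
    out$domain[i] <- b$domain[hit]; out$kind[i] <- b$kind[hit]
    out$bead_slot[i] <- b$slot[hit]
    if (!is.null(iface))
      out$interface[i] <- any(iface$protein == mutations$protein[i] &
                                iface$domain == b$domain[hit] &
                                iface$slot == b$slot[hit])
  }
  out
}

#' Confident-interface residue pairs from complex-prediction output
#'
#' Filters residue pairs to those where both residues are confidently
#' predicted (pLDDT > plddt_min), the pair has an accurate relative
#' prediction (PAE < pae_max), and the pair is at an interface (Ca-Ca
#' distance < dist_max).
#'
#' @param pairs data frame with columns \code{plddt_a, plddt_b, pae,
#'   ca_dist} (plus any identifier columns, which are carried through).
#' @param plddt_min,pae_max,dist_max the three thresholds (70, 5, 10 A).
#' @return The subset of rows passing all three conditions.
#' @export
af2_confident_interface <- function(pairs, plddt_min = 70, pae_max = 5,
                                    dist_max = 10) {
  keep <- pairs$plddt_a > plddt_min & pairs$plddt_b > plddt_min &
    pairs$pae < pae_max & pairs$ca_dist < dist_max
  pairs[keep, , drop = FALSE]
}
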