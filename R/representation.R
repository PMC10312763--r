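#' Bead radius from residue count
#'
#' Radius of a sphere holding \code{n_residues} residues of mean mass
#' \code{mean_residue_mass} at the standard protein density:
#' \eqn{r = (3 M / (4 \pi \rho))^{1/3}} with \eqn{M} the segment mass.
#'
#' @param n_residues number of residues in the bead (>= 1).
#' @param mean_residue_mass mean residue mass in Da (default 110).
#' @param density protein density in g/cm^3 (default 1.35).
#' @return Radius in Angstrom.
#' @export
bead_radius <- function(n_residues, mean_residue_mass = 110, density = 1.35) {
  stopifnot(all(n_residues >= 1))
  mass_da <- n_residues * mean_residue_mass
  # 1 Da = 1.66054e-24 g; 1 cm^3 = 1e24 A^3, so volume [A^3] = M * 1.66054 / rho
  vol <- mass_da * 1.66054 / density
  (3 * vol / (4 * pi))^(1 / 3)
}

#' Tile a residue range into bead segments
#'
#' The trailing bead holds the remainder, so the union of segments equals the
#' range exactly once.
#' @noRd
tile_range <- function(range, rpb) {
  n <- range[2] - range[1] + 1L
  if (n < 1L) stop("empty residue range")
  nb <- ceiling(n / rpb)
  starts <- range[1] + (seq_len(nb) - 1L) * rpb
  ends <- pmin(starts + rpb - 1L, range[2])
  cbind(start = starts, end = ends)
}

#' Build the beads of a flexible domain
#'
#' Coarse-grains a flexible domain into a string of beads of
#' \code{residues_per_bead} residues each (remainder in the last bead). Bead
#' centers are left unset (\code{NA}); they are placed by an initializer.
#'
#' @param domain a \code{\link{domain_spec}} with \code{kind = "flexible"}.
#' @param sequence the protein sequence (used only for bounds checking).
#' @return data frame of beads (res_start, res_end, n_res, radius).
#' @export
build_flexible_beads <- function(domain, sequence) {
  stopifnot(domain$kind == "flexible")
  if (domain$range[2] > nchar(sequence)) stop("domain range outside sequence")
  seg <- tile_range(domain$range, domain$residues_per_bead)
  n_res <- seg[, "end"] - seg[, "start"] + 1L
  data.frame(res_start = seg[, "start"], res_end = seg[, "end"],
             n_res = n_res, radius = bead_radius(n_res))
}

#' Build the beads of a rigid body from reference coordinates
#'
#' One bead per \code{residues_per_bead}-residue segment, centered at the
#' mass-weighted mean of the segment's available residues. Every segment must
#' be covered by at least one residue of the coordinate table.
#'
#' @param domain a \code{\link{domain_spec}} with \code{kind} rigid or fixed.
#' @param coords data frame with columns \code{resno, x, y, z} and optional
#'   \code{mass} (default: equal masses).
#' @return data frame of beads (res_start, res_end, n_res, radius, x, y, z).
#' @export
build_rigid_body <- function(domain, coords) {
  stopifnot(domain$kind %in% c("rigid", "fixed"))
  seg <- tile_range(domain$range, domain$residues_per_bead)
  mass <- coords$mass %||% rep(1, nrow(coords))
  out <- lapply(seq_len(nrow(seg)), function(i) {
    in_seg <- coords$resno >= seg[i, "start"] & coords$resno <= seg[i, "end"]
    if (!any(in_seg))
      stop("no coordinates for segment ", seg[i, "start"], "-", seg[i, "end"],
           " of domain '", domain$name, "'")
    w <- mass[in_seg] / sum(mass[in_seg])
    c(sum(w * coords$x[in_seg]), sum(w * coords$y[in_seg]),
      sum(w * coords$z[in_seg]))
  })
  ctr <- do.call(rbind, out)
  n_res <- seg[, "end"] - seg[, "start"] + 1L
  data.frame(res_start = seg[, "start"], res_end = seg[, "end"], n_res = n_res,
             radius = bead_radius(n_res), x = ctr[, 1], y = ctr[, 2], z = ctr[, 3])
}

#' Sequence-connectivity threshold between two consecutive beads
#'
#' Mixes the globular limit (sum of bead radii) and the disordered limit (a
#' Flory-type end-to-end scaling \eqn{d = c_0 n^\nu} for the n residues
#' spanned between the bead centers) by the protein's disorder fraction:
#' \deqn{t = (1 - f)(r_i + r_j) + f \; c_0 n^\nu .}
#' The spanned residue count is taken as half of each bead's residues.
#'
#' @param f_disorder disorder fraction in [0, 1].
#' @param r_i,r_j bead radii (A).
#' @param n_i,n_j residues in each bead.
#' @param c0,nu disordered-chain scaling constants (defaults 1.93 A, 0.6).
#' @return Threshold distance in Angstrom.
#' @export
connectivity_threshold <- function(f_disorder, r_i, r_j, n_i, n_j,
                                   c0 = 1.93, nu = 0.6) {
  if (any(f_disorder < 0 | f_disorder > 1))
    stop("f_disorder must be in [0, 1]")
  n_link <- (n_i + n_j) / 2
  (1 - f_disorder) * (r_i + r_j) + f_disorder * c0 * n_link^nu
}

#' Build the multi-scale coarse-grained representation of an assembly
#'
#' Expands every protein copy into beads: flexible strings for unstructured
#' domains, rigid bodies (fixed internal geometry) for structured ones, and
#' immobile beads for \code{kind = "fixed"} domains. Rigid and fixed beads get
#' their reference coordinates; flexible bead centers start as \code{NA} and
#' are set by an initializer before sampling.
#'
#' @param topology an \code{\link{assembly_topology}}.
#' @return An \code{assembly_representation}: list with \code{beads} (a data
#'   frame: one row per bead with protein, copy, domain, residue range, radius,
#'   flags), \code{coords} (N x 3 matrix), and \code{rigid_bodies} (list of
#'   bead row indices per body).
#' @export
build_representation <- function(topology) {
  rows <- list(); coords <- list(); bodies <- list()
  body_id <- 0L
  for (p in topology$proteins) {
    for (cp in seq_len(p$copies)) {
      for (d in p$domains) {
        if (d$kind == "flexible") {
          b <- build_flexible_beads(d, p$sequence)
          xyz <- matrix(NA_real_, nrow(b), 3)
          rb <- NA_integer_; mobile <- TRUE
        } else {
          src <- d$structure_source
          if (is.list(src) && !is.data.frame(src))
            src <- read_domain_coords(src$file, src$chain)
          b <- build_rigid_body(d, src)
          xyz <- as.matrix(b[, c("x", "y", "z")])
          if (d$kind == "rigid") {
            body_id <- body_id + 1L
            rb <- body_id; mobile <- TRUE
          } else {
            rb <- NA_integer_; mobile <- FALSE
          }
        }
        nb <- nrow(b)
        rows[[length(rows) + 1L]] <- data.frame(
          protein = p$name, copy = cp, domain = d$name,
          slot = seq_len(nb),
          res_start = b$res_start, res_end = b$res_end, n_res = b$n_res,
          radius = b$radius, kind = d$kind, rigid_body = rep(rb, nb),
          mobile = mobile,
          anchored = d$anchored & seq_len(nb) == 1L,
          em_restrained = d$em_restrained,
          layer = if (is.null(d$layer)) NA_character_ else d$layer,
          stringsAsFactors = FALSE)
        coords[[length(coords) + 1L]] <- xyz
      }
    }
  }
  beads <- do.call(rbind, rows)
  beads$id <- seq_len(nrow(beads))
  beads <- beads[, c("id", setdiff(names(beads), "id"))]
  coords <- do.call(rbind, coords)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  rb_ids <- sort(unique(beads$rigid_body[!is.na(beads$rigid_body)]))
  rigid_bodies <- lapply(rb_ids, function(i) which(beads$rigid_body %in% i))
  names(rigid_bodies) <- rb_ids
  structure(list(beads = beads, coords = coords, rigid_bodies = rigid_bodies,
                 topology = topology),
            class = "assembly_representation")
}

#' @export
print.assembly_representation <- function(x, ...) {
  b <- x$beads
  cat("<assembly_representation> ", nrow(b), " beads, ",
      length(x$rigid_bodies), " rigid bodies, ",
      sum(!b$mobile), " fixed beads\n", sep = "")
  invisible(x)
}

#' Consecutive-bead pairs of a representation
#'
#' Pairs of beads adjacent in sequence within one protein copy (across domain
#' boundaries), with their connectivity thresholds. Pairs internal to one
#' rigid body are flagged: their geometry is immutable so their restraint
#' contribution is a constant.
#' @param rep an \code{assembly_representation}.
#' @param c0,nu scaling constants passed to \code{\link{connectivity_threshold}}.
#' @return data frame (i, j, threshold, intra_body).
#' @export
consecutive_pairs <- function(rep, c0 = 1.93, nu = 0.6) {
  b <- rep$beads
  out <- list()
  for (p in rep$topology$proteins) {
    f <- p$disorder_fraction
    for (cp in seq_len(p$copies)) {
      rows <- which(b$protein == p$name & b$copy == cp)
      rows <- rows[order(b$res_start[rows])]
      if (length(rows) < 2) next
      i <- rows[-length(rows)]; j <- rows[-1]
      thr <- connectivity_threshold(f, b$radius[i], b$radius[j],
                                    b$n_res[i], b$n_res[j], c0, nu)
      intra <- !is.na(b$rigid_body[i]) & !is.na(b$rigid_body[j]) &
        b$rigid_body[i] == b$rigid_body[j]
      out[[length(out) + 1L]] <- data.frame(i = i, j = j, threshold = thr,
                                            intra_body = intra)
    }
  }
  do.call(rbind, out)
}
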