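#' Domain specification
#'
#' Describes one contiguous stretch of a protein sequence and how it is
#' represented: structured domains (\code{kind = "rigid"}) become rigid bodies
#' built from reference coordinates at 30 residues per bead; domains without
#' known structure (\code{kind = "flexible"}) become flexible strings at 20
#' residues per bead; \code{kind = "fixed"} marks domains that are placed from
#' their fitted pose and never moved during sampling (e.g. density-filling
#' copies that only serve to occupy space).
#'
#' @param name short domain label, unique within the protein.
#' @param range length-2 integer vector, 1-based closed residue range.
#' @param kind one of \code{"rigid"}, \code{"flexible"}, \code{"fixed"}.
#' @param residues_per_bead coarse-graining level; defaults to 30 for
#'   rigid/fixed and 20 for flexible domains.
#' @param structure_source for rigid/fixed domains, either a data frame of
#'   per-residue coordinates (columns \code{resno, x, y, z}, optional
#'   \code{mass}) or a list \code{list(file =, chain =)} naming a PDB file to
#'   read with \pkg{bio3d}.
#' @param anchored logical; if \code{TRUE} the membrane-proximal (first) bead
#'   of the domain is constrained to the membrane plane (z fixed) during
#'   sampling. Used for the transmembrane-adjacent bead of a cadherin tail.
#' @param em_restrained logical; whether this domain's beads contribute to the
#'   cryo-EM density restraint.
#' @param layer optional layer label (e.g. \code{"A"} or \code{"B"}) matching a
#'   segmented density layer.
#' @return A \code{domain_spec} list.
#' @export
domain_spec <- function(name, range, kind = c("flexible", "rigid", "fixed"),
                        residues_per_bead = NULL, structure_source = NULL,
                        anchored = FALSE, em_restrained = FALSE, layer = NULL) {
  kind <- match.arg(kind)
  range <- as.integer(range)
  if (length(range) != 2L || any(is.na(range)) || range[2] < range[1] || range[1] < 1L)
    stop("domain '", name, "': range must be a 1-based closed interval (start, end)")
  if (is.null(residues_per_bead))
    residues_per_bead <- if (kind == "flexible") 20L else 30L
  if (kind %in% c("rigid", "fixed") && is.null(structure_source))
    stop("domain '", name, "': ", kind, " domains require a structure_source")
  structure(list(
    name = name, range = range, kind = kind,
    residues_per_bead = as.integer(residues_per_bead),
    structure_source = structure_source,
    anchored = isTRUE(anchored), em_restrained = isTRUE(em_restrained),
    layer = layer
  ), class = "domain_spec")
}

#' Protein specification
#'
#' @param name protein name.
#' @param sequence amino-acid sequence (single string). Only its length is
#'   used by the coarse-grained representation; residue identities are carried
#'   for bookkeeping.
#' @param copies number of copies in the assembly (>= 1).
#' @param domains list of \code{\link{domain_spec}} objects with
#'   non-overlapping residue ranges inside the sequence. Ranges need not cover
#'   the whole sequence: residues outside every domain are not modeled.
#' @param disorder_fraction fraction of the protein predicted disordered, in
#'   [0, 1]; enters the sequence-connectivity threshold.
#' @param interchangeable logical; whether copies of this protein are
#'   equivalent for restraint and RMSD purposes. Proteins whose copies are tied
#'   to fixed landmarks (the density-fitted, immobile copies in their midst)
#'   are matched by index instead.
#' @return An \code{assembly_topology} building block.
#' @export
protein_spec <- function(name, sequence, copies = 1L, domains,
                         disorder_fraction = 0, interchangeable = TRUE) {
  copies <- as.integer(copies)
  if (is.na(copies) || copies < 1L) stop("protein '", name, "': copies must be >= 1")
  if (disorder_fraction < 0 || disorder_fraction > 1)
    stop("protein '", name, "': disorder_fraction must be in [0, 1]")
  nres <- nchar(sequence)
  rng <- t(vapply(domains, function(d) d$range, integer(2)))
  if (any(rng[, 2] > nres))
    stop("protein '", name, "': domain range exceeds sequence length ", nres)
  o <- order(rng[, 1])
  rng <- rng[o, , drop = FALSE]
  if (nrow(rng) > 1 && any(rng[-1, 1] <= rng[-nrow(rng), 2]))
    stop("protein '", name, "': domain ranges overlap")
  structure(list(
    name = name, sequence = sequence, copies = copies,
    domains = domains[o], disorder_fraction = disorder_fraction,
    interchangeable = isTRUE(interchangeable)
  ), class = "protein_spec")
}

#' Assembly topology
#'
#' Bundles the protein specifications of one assembly. The membrane convention
#' throughout the package is: membrane plane at z = 0, cytoplasmic direction
#' +z, cylinder axis = z axis; all distance-to-membrane values are bead-center
#' z coordinates.
#'
#' @param proteins list of \code{\link{protein_spec}} objects.
#' @return An \code{assembly_topology} object.
#' @export
assembly_topology <- function(proteins) {
  nms <- vapply(proteins, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate protein names in topology")
  structure(list(proteins = setNames(proteins, nms)), class = "assembly_topology")
}

#' @export
print.assembly_topology <- function(x, ...) {
  cat("<assembly_topology> ", length(x$proteins), " proteins\n", sep = "")
  for (p in x$proteins) {
    cat(sprintf("  %s: %d res, %d copies, %d domains (%s)\n", p$name,
                nchar(p$sequence), p$copies, length(p$domains),
                paste(vapply(p$domains, function(d)
                  paste0(d$name, ":", d$kind), character(1)), collapse = ", ")))
  }
  invisible(x)
}

#' Write / read a topology as YAML
#'
#' Serializes every field needed to rebuild identical beads (ids, ranges,
#' radii); inline coordinate tables of rigid domains are embedded as lists.
#'
#' @param topology an \code{\link{assembly_topology}}.
#' @param path file path.
#' @return \code{read_topology} returns an \code{assembly_topology}.
#' @export
write_topology <- function(topology, path) {
  ser_dom <- function(d) {
    s <- d$structure_source
    if (is.data.frame(s)) s <- c(list(.inline = TRUE), as.list(s))
    list(name = d$name, range = as.integer(d$range), kind = d$kind,
         residues_per_bead = d$residues_per_bead, structure_source = s,
         anchored = d$anchored, em_restrained = d$em_restrained,
         layer = d$layer)
  }
  obj <- list(proteins = lapply(unname(topology$proteins), function(p) {
    list(name = p$name, sequence = p$sequence, copies = p$copies,
         disorder_fraction = p$disorder_fraction,
         interchangeable = p$interchangeable,
         domains = lapply(p$domains, ser_dom))
  }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  obj <- yaml::read_yaml(path)
  des_dom <- function(d) {
    s <- d$structure_source
    if (!is.null(s) && isTRUE(s$.inline)) {
      s$.inline <- NULL
      s <- as.data.frame(lapply(s, unlist))
    }
    domain_spec(d$name, d$range, d$kind,
                residues_per_bead = d$residues_per_bead, structure_source = s,
                anchored = d$anchored, em_restrained = d$em_restrained,
                layer = d$layer)
  }
  assembly_topology(lapply(obj$proteins, function(p) {
    protein_spec(p$name, p$sequence, p$copies,
                 domains = lapply(p$domains, des_dom),
                 disorder_fraction = p$disorder_fraction,
                 interchangeable = p$interchangeable %||% TRUE)
  }))
}

#' Read reference coordinates for a rigid domain from a PDB file
#'
#' Convenience wrapper around \pkg{bio3d} returning the per-residue C-alpha
#' coordinate table expected by \code{structure_source}.
#'
#' @param file PDB file path.
#' @param chain chain identifier.
#' @return data frame with columns \code{resno, x, y, z}.
#' @export
read_domain_coords <- function(file, chain) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB structure sources requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(file)
  sel <- bio3d::atom.select(pdb, chain = chain, elety = "CA")
  a <- pdb$atom[sel$atom, ]
  data.frame(resno = a$resno, x = a$x, y = a$y, z = a$z)
}
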