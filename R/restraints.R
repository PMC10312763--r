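#' Restraint set constructors
#'
#' Each constructor returns a declarative description of one scoring term;
#' \code{\link{restraint_set}} bundles them with weights and
#' \code{\link{compile_restraints}} turns the bundle plus a representation
#' into an efficient scoring plan. Every term is non-negative and lower is
#' better.
#'
#' @name restraints
NULL

#' Cryo-EM density restraint (one layer)
#'
#' Lognormal agreement between the model density (beads of the matching layer
#' rendered as isotropic Gaussians with sigma = bead radius, mass-weighted)
#' and a Gaussian-mixture approximation of the segmented map layer. For data
#' component k the term is \eqn{0.5 [\log(ov_{MD,k}/ov_{DD,k})]^2/\sigma_{em}^2};
#' both mixtures are normalized to unit mass within the layer so a model
#' mixture identical to the data mixture scores exactly zero.
#'
#' @param gmm a \code{\link{gaussian_mixture}} for the layer.
#' @param layer layer label matching \code{domain_spec$layer}.
#' @param sigma_em lognormal noise scale (dimensionless, default 0.3).
#' @param weight term weight in the total score.
#' @param cap per-component score cap used when the model overlap underflows.
#' @rdname restraints
#' @export
em_restraint <- function(gmm, layer, sigma_em = 0.3, weight = 1, cap = 1e6) {
  structure(list(type = "em", gmm = gmm, layer = layer, sigma_em = sigma_em,
                 weight = weight, cap = cap), class = "restraint")
}

#' Immuno-EM terminus-distance restraint
#'
#' @param records data frame with columns \code{protein, terminus, res_start,
#'   res_end, mean_distance, sem} (one row per restrained terminus; residue
#'   range = antibody-binding region). Distances are bead-center z (membrane
#'   at z = 0).
#' @rdname restraints
#' @export
immuno_em_restraint <- function(records, weight = 1) {
  stopifnot(all(records$sem > 0))
  structure(list(type = "immuno_em", records = records, weight = weight),
            class = "restraint")
}

#' Protein-protein binding restraint
#'
#' Harmonic upper bound on the minimum surface-to-surface distance between the
#' beads of two interacting domains: zero at or below contact, quadratic
#' above. With multiple copies, for each copy of A the minimum over all bead
#' pairs across all copies of B is restrained, and symmetrically for each copy
#' of B, so a copy may pick any partner (several A copies may bind one B).
#'
#' @param records data frame with columns \code{protein_a, res_start_a,
#'   res_end_a, protein_b, res_start_b, res_end_b, assay}.
#' @param k harmonic spring constant.
#' @param assay_weights named vector of relative weights by assay class
#'   (overlay = coIP > Y2H, colocalization).
#' @rdname restraints
#' @export
binding_restraint <- function(records, k = 1,
                              assay_weights = c(overlay = 1, coIP = 1,
                                                Y2H = 0.5, colocalization = 0.5),
                              weight = 1) {
  structure(list(type = "binding", records = records, k = k,
                 assay_weights = assay_weights, weight = weight),
            class = "restraint")
}

#' Cylindrical confinement restraint
#' @param radius cylinder radius in Angstrom (default 150, enclosing the map).
#' @rdname restraints
#' @export
cylinder_restraint <- function(radius = 150, k = 1, weight = 1) {
  stopifnot(radius > 0)
  structure(list(type = "cylinder", radius = radius, k = k, weight = weight),
            class = "restraint")
}

#' Excluded-volume restraint
#'
#' Pairs overlapping by \eqn{o = \max(0, r_i + r_j - d)} are penalized
#' \eqn{k o^2}. Pairs within one rigid body and consecutive-in-sequence pairs
#' are exempt (the former are immutable, the latter are governed by the
#' connectivity restraint).
#' @rdname restraints
#' @export
excluded_volume_restraint <- function(k = 1, weight = 1) {
  structure(list(type = "excluded_volume", k = k, weight = weight),
            class = "restraint")
}

#' Sequence-connectivity restraint
#' @param c0,nu disordered-linker scaling constants, see
#'   \code{\link{connectivity_threshold}}.
#' @rdname restraints
#' @export
connectivity_restraint <- function(k = 1, c0 = 1.93, nu = 0.6, weight = 1) {
  structure(list(type = "connectivity", k = k, c0 = c0, nu = nu,
                 weight = weight), class = "restraint")
}

#' Bundle restraints into a set
#' @param ... \code{restraint} objects.
#' @return A \code{restraint_set} (list of restraints).
#' @export
restraint_set <- function(...) {
  rs <- list(...)
  stopifnot(all(vapply(rs, inherits, logical(1), "restraint")))
  structure(rs, class = "restraint_set")
}

score_term_names <- c("em", "immuno_em", "binding", "cylinder",
                      "excluded_volume", "connectivity")

#' Compile a restraint set against a representation
#'
#' Precomputes all index structures (excluded-volume pairs, connectivity pairs
#' and thresholds, per-layer density components and their self-overlaps,
#' per-record bead lists) so that scoring a configuration is a handful of
#' vectorized kernel calls.
#'
#' @param rep an \code{\link{assembly_representation}}.
#' @param rset a \code{\link{restraint_set}}.
#' @param enforce_positive_z reject configurations with mobile beads below the
#'   membrane plane during sampling (the score itself does not penalize z < 0).
#' @return A \code{restraint_plan} with a \code{$score(coords)} function
#'   returning the named per-term score vector.
#' @export
compile_restraints <- function(rep, rset, enforce_positive_z = TRUE) {
  b <- rep$beads
  n <- nrow(b)
  plan <- list(rep = rep, enforce_positive_z = enforce_positive_z)
  weights <- setNames(rep_len(0, length(score_term_names)), score_term_names)
  cpairs <- NULL
  get_cpairs <- function(c0, nu) consecutive_pairs(rep, c0, nu)

  for (r in rset) {
    weights[r$type] <- r$weight
    if (r$type == "excluded_volume") {
      pr <- t(combn(n, 2))
      same_body <- !is.na(b$rigid_body[pr[, 1]]) &
        !is.na(b$rigid_body[pr[, 2]]) &
        b$rigid_body[pr[, 1]] == b$rigid_body[pr[, 2]]
      cp <- consecutive_pairs(rep)
      consec <- paste(pr[, 1], pr[, 2]) %in%
        c(paste(cp$i, cp$j), paste(cp$j, cp$i))
      keep <- !(same_body | consec)
      plan$ev <- list(i = pr[keep, 1], j = pr[keep, 2], k = r$k)
    } else if (r$type == "connectivity") {
      cp <- get_cpairs(r$c0, r$nu)
      dyn <- !cp$intra_body
      const_score <- conn_score_cpp(rep$coords, cp$i[!dyn], cp$j[!dyn],
                                    cp$threshold[!dyn], r$k)
      plan$conn <- list(i = cp$i[dyn], j = cp$j[dyn],
                        thr = cp$threshold[dyn], k = r$k,
                        constant = const_score)
      cpairs <- cp
    } else if (r$type == "cylinder") {
      plan$cyl <- list(idx = which(b$mobile), radius = r$radius, k = r$k)
    } else if (r$type == "em") {
      idx <- which(b$em_restrained & !is.na(b$layer) & b$layer == r$layer)
      if (!length(idx)) stop("no em_restrained beads for layer '", r$layer, "'")
      bw <- b$n_res[idx] / sum(b$n_res[idx])
      comp <- r$gmm$components
      mu <- as.matrix(comp[, c("x", "y", "z")])
      ovdd <- as.numeric(overlap_matrix(mu, comp$sigma, mu, comp$sigma) %*%
                           comp$weight)
      plan$em <- c(plan$em %||% list(),
                   list(list(idx = idx, bw = bw, mu = mu, ds = comp$sigma,
                             dw = comp$weight, ovdd = ovdd,
                             sigma_em = r$sigma_em, cap = r$cap)))
    } else if (r$type == "immuno_em") {
      recs <- lapply(seq_len(nrow(r$records)), function(ri) {
        rec <- r$records[ri, ]
        pb <- which(b$protein == rec$protein &
                      b$res_end >= rec$res_start & b$res_start <= rec$res_end)
        if (!length(pb))
          stop("immuno-EM record ", ri, " (", rec$protein,
               "): no bead overlaps the antibody-binding range")
        copies <- sort(unique(b$copy[pb]))
        list(copy_idx = lapply(copies, function(cp) pb[b$copy[pb] == cp]),
             mean_d = rec$mean_distance, sem = rec$sem)
      })
      plan$immuno <- recs
    } else if (r$type == "binding") {
      recs <- lapply(seq_len(nrow(r$records)), function(ri) {
        rec <- r$records[ri, ]
        ba <- which(b$protein == rec$protein_a &
                      b$res_end >= rec$res_start_a &
                      b$res_start <= rec$res_end_a)
        bb <- which(b$protein == rec$protein_b &
                      b$res_end >= rec$res_start_b &
                      b$res_start <= rec$res_end_b)
        if (!length(ba) || !length(bb))
          stop("binding record ", ri, ": domain not in representation")
        w <- unname(r$assay_weights[as.character(rec$assay)])
        if (is.na(w)) w <- 1
        list(a_by_copy = split(ba, b$copy[ba]),
             b_by_copy = split(bb, b$copy[bb]),
             a_all = ba, b_all = bb, w = w, k = r$k)
      })
      plan$binding <- recs
    }
  }
  plan$weights <- weights
  plan$radii <- b$radius
  plan$mobile_idx <- which(b$mobile)
  plan$score <- function(coords) score_terms(plan, coords)
  class(plan) <- "restraint_plan"
  plan
}

#' Score all terms of a plan for one configuration
#' @noRd
score_terms <- function(plan, coords) {
  s <- setNames(numeric(length(score_term_names)), score_term_names)
  if (!is.null(plan$ev))
    s["excluded_volume"] <- ev_score_cpp(coords, plan$radii, plan$ev$i,
                                         plan$ev$j, plan$ev$k)
  if (!is.null(plan$conn))
    s["connectivity"] <- plan$conn$constant +
      conn_score_cpp(coords, plan$conn$i, plan$conn$j, plan$conn$thr,
                     plan$conn$k)
  if (!is.null(plan$cyl))
    s["cylinder"] <- cyl_score_cpp(coords, plan$cyl$idx, plan$cyl$radius,
                                   plan$cyl$k)
  if (!is.null(plan$em))
    s["em"] <- sum(vapply(plan$em, function(e)
      em_score_cpp(coords, plan$radii, e$idx, e$bw, e$mu, e$ds, e$ovdd,
                   e$sigma_em, e$cap), numeric(1)))
  if (!is.null(plan$immuno))
    s["immuno_em"] <- sum(vapply(plan$immuno, function(r)
      immuno_score_cpp(coords, r$copy_idx, r$mean_d, r$sem), numeric(1)))
  if (!is.null(plan$binding))
    s["binding"] <- sum(vapply(plan$binding, function(r) {
      ta <- sum(vapply(r$a_by_copy, function(ix) {
        d <- min_surface_dist_cpp(coords, plan$radii, ix, r$b_all)
        r$w * r$k * max(0, d)^2
      }, numeric(1)))
      tb <- sum(vapply(r$b_by_copy, function(ix) {
        d <- min_surface_dist_cpp(coords, plan$radii, ix, r$a_all)
        r$w * r$k * max(0, d)^2
      }, numeric(1)))
      ta + tb
    }, numeric(1)))
  s
}

#' Total score report for a configuration
#'
#' @param coords N x 3 coordinate matrix.
#' @param plan a compiled \code{restraint_plan}.
#' @return A \code{score_report}: list with per-term scores (\code{terms}),
#'   the term weights, and \code{total} = sum of weights * terms.
#' @export
total_score <- function(coords, plan) {
  terms <- plan$score(coords)
  structure(list(terms = terms, weights = plan$weights,
                 total = sum(plan$weights * terms)),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat("<score_report> total =", signif(x$total, 6), "\n")
  print(signif(x$terms, 6))
  invisible(x)
}

# ---- CSV interfaces ---------------------------------------------------------

#' Read / write immuno-EM and binding tables
#'
#' Documented CSV headers: immuno-EM tables have columns \code{protein,
#' terminus, res_start, res_end, mean_distance, sem}; binding tables have
#' \code{protein_a, res_start_a, res_end_a, protein_b, res_start_b,
#' res_end_b, assay}.
#'
#' @param path CSV file.
#' @return A data frame with the validated columns.
#' @export
read_immuno_em_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein", "terminus", "res_start", "res_end", "mean_distance", "sem")
  if (!all(need %in% names(x))) stop("immuno-EM CSV must have columns: ",
                                     paste(need, collapse = ", "))
  if (any(x$sem <= 0)) stop("immuno-EM sem must be > 0")
  x
}

#' @rdname read_immuno_em_csv
#' @export
read_binding_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein_a", "res_start_a", "res_end_a",
            "protein_b", "res_start_b", "res_end_b", "assay")
  if (!all(need %in% names(x))) stop("binding CSV must have columns: ",
                                     paste(need, collapse = ", "))
  x
}
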