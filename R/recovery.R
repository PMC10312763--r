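#' Configuration of the toy recovery experiment
#'
#' Pipeline settings used by \code{\link{recovery_experiment}}: simulation
#' noise, density-fit size, restraint weights, sampling budget and analysis
#' thresholds. The defaults are sized for a desk-scale run (minutes per
#' seed).
#'
#' @param n_runs independent sampling runs per seed.
#' @param n_sweeps Gibbs sweeps per replica.
#' @param save_period frame saving period (sweeps).
#' @param n_replicas,t_max replica ladder (geometric, t_min = 1).
#' @param gmm_k mixture components per layer; \code{NULL} = number of
#'   density-restrained beads in the layer.
#' @param sigma_em EM restraint noise scale.
#' @param sem immuno-EM noise (A).
#' @param contact_cutoff contact-map cutoff (A).
#' @param sig_threshold significant-contact frequency threshold.
#' @export
recovery_config <- function(n_runs = 3, n_sweeps = 600, save_period = 10,
                            n_replicas = 4, t_max = 2.5, gmm_k = NULL,
                            sigma_em = 0.3, sem = 5, contact_cutoff = 10,
                            sig_threshold = 0.25) {
  as.list(environment())
}

#' Build the restraint plan for a simulated toy dataset
#' @noRd
toy_restraint_plan <- function(rep_, truth_spec, gmms, immuno, binding,
                               config) {
  rset <- restraint_set(
    em_restraint(gmms$A, "A", sigma_em = config$sigma_em),
    em_restraint(gmms$B, "B", sigma_em = config$sigma_em),
    immuno_em_restraint(immuno),
    binding_restraint(binding),
    cylinder_restraint(radius = truth_spec$cyl_radius),
    excluded_volume_restraint(),
    connectivity_restraint())
  compile_restraints(rep_, rset)
}

#' Molecule-wise centroids from a layer mixture
#'
#' Groups the mixture components into \code{n} molecules by k-means on the
#' component means and returns the weighted group centers.
#' @param gmm a \code{\link{gaussian_mixture}}; @param n molecules.
#' @param seed seed for k-means restarts.
#' @export
molecule_centroids <- function(gmm, n, seed = 1) {
  mu <- as.matrix(gmm$components[, c("x", "y", "z")])
  if (nrow(mu) <= n) return(mu[seq_len(min(n, nrow(mu))), , drop = FALSE])
  km <- with_seed(seed, kmeans(mu, centers = n, nstart = 10))
  km$centers
}

#' Layer-aware initializer for the toy assembly
#'
#' arm molecules are initialized around molecule-wise lower-layer densities,
#' plak molecules are randomized (with immuno-EM polarity correction) inside
#' a box around the upper-layer density, and anc chains start anchored on the
#' membrane plane. Everything the initializer uses is derived from the
#' simulated data, not from the ground truth.
#' @noRd
toy_initializer <- function(gmms, immuno, truth_spec, config) {
  function(rep_, seed) {
    coords <- rep_$coords
    cen <- molecule_centroids(gmms$A, rep_$topology$proteins[["arm"]]$copies,
                              seed = seed)
    coords <- initialize_pkp_layer(rep_, coords, "arm", cen)
    mu <- as.matrix(gmms$B$components[, c("x", "y", "z")])
    pad <- 15
    box <- list(min = apply(mu, 2, min) - pad, max = apply(mu, 2, max) + pad)
    imm_p <- immuno[immuno$protein == "plak", ]
    pol <- if (imm_p$mean_distance[imm_p$terminus == "N"] <=
               imm_p$mean_distance[imm_p$terminus == "C"]) "N" else "C"
    coords <- initialize_pg_layer(rep_, coords, "plak", box,
                                  polarity = c(plak = pol))
    initialize_anchored_chain(rep_, coords, "anc", truth_spec$cyl_radius)
  }
}

#' Domain-pair level significant-contact calls
#'
#' Aggregates bead-pair calls of \code{\link{significant_contacts}} across
#' all distinct protein pairs to the domain-pair level.
#' @noRd
domain_pair_calls <- function(ens, config) {
  prots <- names(ens$rep$topology$proteins)
  calls <- list()
  for (i in seq_len(length(prots) - 1)) for (j in (i + 1):length(prots)) {
    cm <- contact_map(ens, prots[i], prots[j], cutoff = config$contact_cutoff)
    sc <- significant_contacts(cm, config$sig_threshold)
    if (nrow(sc$calls))
      calls[[length(calls) + 1L]] <- unique(data.frame(
        protein_a = prots[i], domain_a = sc$calls$domain_a,
        protein_b = prots[j], domain_b = sc$calls$domain_b))
  }
  if (!length(calls)) return(data.frame())
  unique(do.call(rbind, calls))
}

#' Run the full pipeline once on simulated data
#'
#' Generates a ground truth, simulates its density maps, immuno-EM and
#' binding tables, samples with the full six-term score, applies the
#' analysis protocol (equilibration filter, score-space clustering,
#' good-scoring filter, exhaustiveness test, structural clustering), and
#' scores recovery against the planted truth.
#'
#' @param seed integer seed (drives truth, noise and sampling).
#' @param spec a \code{\link{toy_spec}}.
#' @param config a \code{\link{recovery_config}}.
#' @return List with the cluster result and recovery metrics: model
#'   precision, ambiguity-aware centroid-to-truth RMSD, planted-contact
#'   recall, false domain-pair calls, exhaustiveness report, and the cluster
#'   ensemble.
#' @export
recover_once <- function(seed, spec = toy_spec(), config = recovery_config()) {
  truth <- generate_toy_assembly(spec, sub_seed(seed, 1))
  maps <- list(A = simulate_density_map(truth, "A"),
               B = simulate_density_map(truth, "B"))
  b <- truth$rep$beads
  k_layer <- function(l) config$gmm_k %||%
    sum(b$em_restrained & b$layer %in% l)
  gmms <- list(A = fit_gmm_to_map(maps$A, k_layer("A"), sub_seed(seed, 2)),
               B = fit_gmm_to_map(maps$B, k_layer("B"), sub_seed(seed, 2)))
  immuno <- simulate_immuno_em(truth, config$sem, sub_seed(seed, 3))
  binding <- simulate_binding_data(truth, seed = sub_seed(seed, 4))
  rep_ <- build_representation(truth$topology)
  plan <- toy_restraint_plan(rep_, spec, gmms, immuno, binding, config)
  init <- toy_initializer(gmms, immuno, spec, config)
  ens <- run_sampling(plan, init,
                      ladder = replica_ladder(config$n_replicas,
                                              t_max = config$t_max),
                      run = sampling_run(config$n_sweeps, config$save_period),
                      n_runs = config$n_runs, seed = sub_seed(seed, 5))
  filt <- equilibration_filter(ens)
  filt <- score_space_cluster(filt)
  good <- good_scoring_filter(filt)
  grouping <- rmsd_grouping(rep_)
  rmat <- rmsd_matrix(good, grouping)
  ex <- exhaustiveness_test(good, rmsd_mat = rmat, split = "run",
                            seed = sub_seed(seed, 6))
  thr <- if (!is.na(ex$sampling_precision)) ex$sampling_precision else
    max(ex$tests$threshold)
  cl <- structural_cluster(good, thr, rmat)
  major <- subset_ensemble(good, which(cl$labels == cl$major))
  centroid_rmsd <- ambiguous_rmsd(good$frames[[cl$major_centroid]],
                                  truth$coords, grouping)
  calls <- domain_pair_calls(major, config)
  key <- function(d) paste(d$protein_a, d$domain_a, d$protein_b, d$domain_b)
  planted <- key(truth$contacts)
  called <- if (nrow(calls)) key(calls) else character(0)
  cc <- vapply(c(A = "A", B = "B"), function(l) {
    prot <- if (l == "A") "arm" else "plak"
    ld <- localization_density(major, prot, "core", voxel = maps[[l]]$voxel)
    density_cross_correlation(ld, maps[[l]])
  }, numeric(1))
  list(truth = truth, ensemble_size = n_frames(ens),
       good_size = n_frames(good), exhaustiveness = ex, cluster = cl,
       major = major,
       model_precision = cl$model_precision,
       centroid_rmsd = centroid_rmsd,
       density_cc = cc,
       planted_contacts = planted, called_contacts = called,
       contact_recall = mean(planted %in% called),
       false_calls = sum(!called %in% planted))
}

#' Recovery experiment over several seeds
#'
#' Repeats \code{\link{recover_once}} and summarizes: per-seed model
#' precision, centroid-to-truth RMSD, contact recall and false calls, plus
#' the fraction of seeds where the centroid-to-truth RMSD is below the model
#' precision and the planted contacts are recovered exactly.
#'
#' @param seeds integer seeds.
#' @param spec,config see \code{\link{recover_once}}.
#' @param progress print one line per seed.
#' @return List: \code{per_seed} data frame and \code{runs} (full results).
#' @export
recovery_experiment <- function(seeds, spec = toy_spec(),
                                config = recovery_config(),
                                progress = FALSE) {
  runs <- lapply(seeds, function(s) {
    r <- recover_once(s, spec, config)
    if (progress)
      message(sprintf(
        "seed %d: precision %.1f A, centroid RMSD %.1f A, recall %.2f, false %d",
        s, r$model_precision, r$centroid_rmsd, r$contact_recall, r$false_calls))
    r
  })
  per_seed <- data.frame(
    seed = seeds,
    model_precision = vapply(runs, `[[`, numeric(1), "model_precision"),
    centroid_rmsd = vapply(runs, `[[`, numeric(1), "centroid_rmsd"),
    contact_recall = vapply(runs, `[[`, numeric(1), "contact_recall"),
    false_calls = vapply(runs, `[[`, numeric(1), "false_calls"),
    density_cc_a = vapply(runs, function(r) r$density_cc[["A"]], numeric(1)),
    density_cc_b = vapply(runs, function(r) r$density_cc[["B"]], numeric(1)),
    sampling_precision = vapply(runs, function(r)
      r$cluster$sampling_precision, numeric(1)),
    exhaustive = vapply(runs, function(r) r$exhaustiveness$pass, logical(1)),
    major_size = vapply(runs, function(r) max(r$cluster$sizes), numeric(1)),
    good_size = vapply(runs, `[[`, numeric(1), "good_size"))
  per_seed$recovered <- per_seed$centroid_rmsd < per_seed$model_precision &
    per_seed$contact_recall == 1 & per_seed$false_calls == 0
  list(per_seed = per_seed, runs = runs)
}
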