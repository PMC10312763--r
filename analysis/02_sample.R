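#!/usr/bin/env Rscript
# Step 2 — replica-exchange Gibbs sampling against the simulated data.
#
# Reads the inputs written by 01_simulate.R, compiles the six-term scoring
# function, initializes layer-aware (lower-layer molecules on their density
# centroids, upper-layer molecules randomized in a polarity-checked box,
# anchored chains on the membrane) and samples. The trajectory goes to
# results/trajectory.csv.

suppressPackageStartupMessages(library(desmodel))

seed <- 7
topo <- read_topology("results/inputs/topology.yaml")
rep_ <- build_representation(topo)
maps <- list(A = read_mrc("results/inputs/layer_A.mrc"),
             B = read_mrc("results/inputs/layer_B.mrc"))
immuno <- read_immuno_em_csv("results/inputs/immuno_em.csv")
binding <- read_binding_csv("results/inputs/binding.csv")

b <- rep_$beads
gmms <- lapply(c(A = "A", B = "B"), function(l)
  fit_gmm_to_map(maps[[l]], K = sum(b$em_restrained & b$layer %in% l),
                 seed = sub_seed(seed, 2)))

plan <- compile_restraints(rep_, restraint_set(
  em_restraint(gmms$A, "A", sigma_em = 0.3),
  em_restraint(gmms$B, "B", sigma_em = 0.3),
  immuno_em_restraint(immuno),
  binding_restraint(binding),
  cylinder_restraint(radius = 60),
  excluded_volume_restraint(),
  connectivity_restraint()))

init <- function(rep_, seed) {
  co <- rep_$coords
  cen <- molecule_centroids(gmms$A, topo$proteins[["arm"]]$copies, seed)
  co <- initialize_pkp_layer(rep_, co, "arm", cen)
  mu <- as.matrix(gmms$B$components[, c("x", "y", "z")])
  box <- list(min = apply(mu, 2, min) - 15, max = apply(mu, 2, max) + 15)
  imm_p <- immuno[immuno$protein == "plak", ]
  pol <- if (imm_p$mean_distance[imm_p$terminus == "N"] <=
             imm_p$mean_distance[imm_p$terminus == "C"]) "N" else "C"
  co <- initialize_pg_layer(rep_, co, "plak", box, polarity = c(plak = pol))
  initialize_anchored_chain(rep_, co, "anc", 60)
}

message("sampling: 3 runs x 4 replicas x 600 sweeps ...")
t0 <- Sys.time()
ens <- run_sampling(plan, init,
                    ladder = replica_ladder(4, t_max = 2.5),
                    run = sampling_run(600, save_period = 10),
                    n_runs = 3, seed = seed, progress = TRUE)
message(sprintf("sampled %d frames in %.1f min; mean acceptance %.2f",
                n_frames(ens),
                as.numeric(difftime(Sys.time(), t0, units = "mins")),
                mean(ens$acceptance)))
write_trajectory(ens, "results/trajectory.csv")
message("trajectory written to results/trajectory.csv")
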