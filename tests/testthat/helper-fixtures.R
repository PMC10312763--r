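# Small fixtures built in code: a minimal two-protein representation and
# random configurations over it.

aa_seq <- function(n) paste(rep_len(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n),
                            collapse = "")

# straight-line reference coordinates: one residue per Angstrom along z
line_coords <- function(n, spacing = 1) {
  data.frame(resno = seq_len(n), x = 0, y = 0, z = (seq_len(n) - 1) * spacing)
}

# pa: rigid 60-res domain (2 beads, density-restrained, layer L)
# pb: flexible 40-res chain (2 beads), 2 copies, anchored
mini_topology <- function(copies_b = 2, fixed_a = FALSE) {
  assembly_topology(list(
    protein_spec("pa", aa_seq(60), copies = 1, disorder_fraction = 0.2,
                 domains = list(domain_spec("core", c(1, 60),
                                            if (fixed_a) "fixed" else "rigid",
                                            structure_source = line_coords(60),
                                            em_restrained = TRUE,
                                            layer = "L"))),
    protein_spec("pb", aa_seq(40), copies = copies_b, disorder_fraction = 0.5,
                 domains = list(domain_spec("tail", c(1, 40), "flexible",
                                            anchored = TRUE)))
  ))
}

mini_rep <- function(...) build_representation(mini_topology(...))

# random positive-z configuration over a representation
rand_config <- function(rep_, seed, spread = 40) {
  withr::with_seed(seed, {
    co <- rep_$coords
    n <- nrow(co)
    co[] <- cbind(runif(n, -spread, spread), runif(n, -spread, spread),
                  runif(n, 0, 2 * spread))
    # keep rigid bodies internally rigid: place via random transform
    for (body in rep_$rigid_bodies) {
      local <- sweep(rep_$coords[body, , drop = FALSE], 2,
                     colMeans(rep_$coords[body, , drop = FALSE]))
      R <- desmodel:::rand_rotation()
      ctr <- c(runif(2, -spread, spread), runif(1, spread / 2, 2 * spread))
      co[body, ] <- sweep(local %*% t(R), 2, ctr, "+")
    }
    co
  })
}

# a compiled plan over mini_rep with every term active
mini_plan <- function(rep_, seed = 1) {
  gmm <- gaussian_mixture(weight = c(0.5, 0.5), x = c(-5, 5), y = c(0, 0),
                          z = c(20, 30), sigma = c(8, 8))
  immuno <- data.frame(protein = "pb", terminus = "C", res_start = 21,
                       res_end = 40, mean_distance = 30, sem = 5)
  binding <- data.frame(protein_a = "pa", res_start_a = 1, res_end_a = 60,
                        protein_b = "pb", res_start_b = 1, res_end_b = 40,
                        assay = "Y2H")
  compile_restraints(rep_, restraint_set(
    em_restraint(gmm, "L", sigma_em = 0.5),
    immuno_em_restraint(immuno),
    binding_restraint(binding),
    cylinder_restraint(radius = 50),
    excluded_volume_restraint(),
    connectivity_restraint()))
}

# single-mobile-bead representation for sampler statistics
one_bead_rep <- function() {
  build_representation(assembly_topology(list(
    protein_spec("solo", aa_seq(20), copies = 1,
                 domains = list(domain_spec("d", c(1, 20), "flexible"))))))
}

# plan-like object with an arbitrary score function (for sampler tests)
score_plan <- function(rep_, f, positive_z = FALSE) {
  structure(list(rep = rep_, enforce_positive_z = positive_z,
                 weights = c(custom = 1),
                 score = function(coords) c(custom = f(coords))),
            class = "restraint_plan")
}
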