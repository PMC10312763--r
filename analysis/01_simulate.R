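#!/usr/bin/env Rscript
# Step 1 — build the synthetic study system.
#
# Generates the planted two-layer toy assembly and every pseudo-experimental
# input the modeling pipeline consumes: segmented per-layer density maps
# (MRC), an immuno-EM terminus-distance table and a protein-protein binding
# table (CSV), plus the topology (YAML). Everything downstream reads only
# these files.

suppressPackageStartupMessages(library(desmodel))

seed <- 7
dir.create("results/inputs", showWarnings = FALSE, recursive = TRUE)

truth <- generate_toy_assembly(seed = seed)
message("ground truth: ", nrow(truth$rep$beads), " beads, ",
        nrow(truth$contacts), " planted domain contacts")

write_topology(truth$topology, "results/inputs/topology.yaml")

for (layer in c("A", "B")) {
  m <- simulate_density_map(truth, layer)
  write_mrc(m, sprintf("results/inputs/layer_%s.mrc", layer))
  message(sprintf("layer %s map: %s voxels, mass %.0f", layer,
                  paste(dim(m$data), collapse = "x"), map_mass(m)))
}

immuno <- simulate_immuno_em(truth, sem = 5, seed = sub_seed(seed, 3))
write.csv(immuno, "results/inputs/immuno_em.csv", row.names = FALSE)

binding <- simulate_binding_data(truth, seed = sub_seed(seed, 4))
write.csv(binding, "results/inputs/binding.csv", row.names = FALSE)
message("simulated ", nrow(immuno), " immuno-EM records and ",
        nrow(binding), " binding records")

# keep the truth for the final comparison (plain CSV of bead coordinates)
write.csv(cbind(truth$rep$beads[, c("id", "protein", "copy", "domain",
                                    "slot", "radius")],
                as.data.frame(truth$coords)),
          "results/inputs/truth_coords.csv", row.names = FALSE)
write.csv(truth$contacts, "results/inputs/truth_contacts.csv",
          row.names = FALSE)
message("inputs written under results/inputs/")
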