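# desmodel

Bayesian integrative structure determination for layered, membrane-anchored
protein assemblies — the setting typified by the desmosomal outer dense
plaque (ODP), where plakophilin- and plakoglobin-rich layers stack above the
plasma membrane, much of the sequence is disordered, and no single experiment
resolves the architecture.

`desmodel` is for structural/computational biologists who have heterogeneous,
low-resolution evidence — a segmented electron-density map per layer,
immuno-EM gold-label distances of protein termini from the membrane,
domain-level protein–protein binding assays, atomic structures for a few
folded domains — and want a tested, reproducible pipeline that turns that
evidence into an ensemble of coarse-grained models with honest precision
estimates.

## What it implements

* **Multi-scale bead representation.** Structured domains become rigid bodies
  at 30 residues/bead (from reference coordinates); unstructured domains
  become flexible bead strings at 20 residues/bead; bead radii follow
  r = (3M/4πρ)^(1/3) at standard protein density.
* **A six-term scoring function** (all terms ≥ 0, lower is better):
  a Gaussian-mixture cryo-EM density restraint per layer with a lognormal
  overlap score ½ log²(ov_MD/ov_DD)/σ²; an immuno-EM restraint
  ½((z* − μ)/sem)² on the antibody-range bead closest to the measured mean,
  per copy; a harmonic upper bound on the minimum surface distance between
  interacting domains (copy-ambiguous: each copy may bind any partner
  copy); cylindrical confinement; excluded volume; and sequence connectivity
  with disorder-aware thresholds (1 − f)(r_i + r_j) + f·c₀n^ν.
* **Replica-exchange Gibbs Monte Carlo** over bead translations, rigid-body
  and whole-protein moves, with a membrane anchoring constraint
  (anchored beads move only in the membrane plane), fixed density-filling
  copies, polarity-checked randomized initialization of the upper layer, and
  density-centroid initialization of the lower layer.
* **The ensemble analysis protocol**: score equilibration/autocorrelation
  filtering, density-based clustering in restraint-score space, the
  mean + 1.46 SD good-scoring filter, the two-half sampling-exhaustiveness
  test (KS on scores; chi-square/Cramér's V on cluster populations across a
  threshold ladder), greedy structural clustering with an ambiguity-aware
  RMSD (assignment problem over copy pairings, no superposition), model
  precision, and per-domain localization probability densities (MRC output).
* **Validation tools**: fits to used and held-out data, contact maps
  (10 Å surface cutoff, any-copy semantics) with significant-interface calls
  at the 20–25 % frequency threshold, a dSTORM plaque-to-plaque transform,
  cadherin spacing, mutation-to-bead mapping, and the confident-interface
  rule for complex predictions (pLDDT > 70, PAE < 5, Cα–Cα < 10 Å).
* **A synthetic-data module** that plants a two-layer toy assembly with known
  ground truth (exact-tangency contacts, zero stereochemical violations) and
  simulates every input the pipeline consumes, so the whole method is
  verifiable end to end without any external data.

File formats: MRC/CCP4 density maps, CSV data tables with documented headers,
YAML topologies, CSV trajectories, multi-model PDB export of bead models.

## Worked example

The `analysis/` scripts run the full study on the synthetic assembly
(3 proteins × 2 copies, 30 beads, a 60 Å cylinder with two 40 Å layers,
4 planted domain–domain contacts):

```sh
Rscript analysis/01_simulate.R   # truth + maps + immuno-EM + binding tables
Rscript analysis/02_sample.R    # 3 runs x 4 replicas x 600 sweeps
Rscript analysis/03_analyze.R   # filters, exhaustiveness, clustering
Rscript analysis/04_validate.R  # fits, contact maps, recovery vs truth
```

Printed output of the analysis steps (every step is seeded, so a rerun
reproduces these numbers exactly):

```
ground truth: 30 beads, 4 planted domain contacts
simulated 6 immuno-EM records and 4 binding records
sampling: 3 runs x 4 replicas x 600 sweeps ...
sampled 720 frames in 1.6 min; mean acceptance 0.41
after equilibration/autocorrelation filter: 330
largest score-space cluster: 303
good-scoring set: 239
exhaustiveness: KS p = 0.166; sampling precision = 25.8 A
3 cluster(s); major cluster 233 of 239 models; model precision 19.5 A
binding-data satisfaction (fraction of models in contact):
  record protein_a protein_b median_min_distance satisfied
1      1       anc       arm          -0.35           0.74
2      2       anc       arm          -0.59           0.85
3      3       anc      plak          -0.40           0.79
4      4       arm      plak          -0.51           0.84
layer A density cross-correlation: 0.92
layer B density cross-correlation: 0.89
planted contact recall: 1.00; false domain-pair calls: 0
centroid-to-truth RMSD 17.6 A vs model precision 19.5 A
```

Reading the numbers: the *sampling precision* is the smallest clustering
threshold at which two independent halves of the ensemble are statistically
indistinguishable; the *model precision* is the mean ambiguity-aware RMSD of
major-cluster members to their centroid, i.e. the structural uncertainty of
the result. Recovery is demonstrated because the centroid sits closer to the
planted truth than that uncertainty, every planted contact is recalled at the
25 % contact-frequency threshold, and no spurious domain pair is called.

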