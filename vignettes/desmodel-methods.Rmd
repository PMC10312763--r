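---
title: "Integrative modeling of layered membrane plaques: models, restraints and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative modeling of layered membrane plaques: models, restraints and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large membrane-proximal protein assemblies such as the desmosomal outer dense
plaque (ODP) resist single-technique structure determination: the constituent
proteins are hard to purify, a large fraction of their sequence is
disordered, and the available cryo-electron tomograms resolve only layer-level
architecture (tens of Angstrom). What *is* available is heterogeneous:
low-resolution segmented densities for each layer, immuno-EM gold-label
distances of protein termini from the plasma membrane, domain-level
protein-protein binding evidence from biochemical assays, atomic structures
for a few folded domains, and generic stereochemistry. `desmodel` implements
a Bayesian-flavored integrative approach for this setting: encode each
information source as a spatial restraint over a coarse-grained bead model,
sample configurations by replica-exchange Gibbs Monte Carlo, and subject the
resulting ensemble to a standardized analysis and validation protocol.

The package is organized as a pipeline (the `analysis/` scripts in the source
repository run it end to end) but every step is an ordinary exported function
operating on plain R objects, so each stage can be tested and reused in
isolation.

## Representation

Each protein copy is a chain of spherical beads along the backbone.

* Domains with known atomic structure are coarse-grained at **30 residues per
  bead** and treated as **rigid bodies**: the bead centers are segment
  centroids of the reference coordinates and their relative geometry is fixed
  during sampling.
* Domains without known structure are coarse-grained at **20 residues per
  bead** and sampled as **flexible strings**; the trailing bead absorbs the
  remainder of the division, so bead residue ranges tile each domain exactly
  once.
* A domain may also be marked `fixed`: its beads are placed from a fitted
  pose and never moved. This mirrors density-filling copies whose only role
  is to occupy space (and which also pin the copy identity of their protein,
  see *Ambiguity* below).

Bead radii follow from the residue count assuming a standard protein density
of 1.35 g/cm^3 and a mean residue mass of 110 Da,
\(r = (3M/4\pi\rho)^{1/3}\); both constants are arguments of `bead_radius()`.

The membrane defines the coordinate frame throughout: the plasma membrane is
the plane \(z = 0\), the cytoplasm is \(+z\), and the confinement cylinder
axis is the \(z\) axis. All "distance to membrane" quantities are bead-center
\(z\) values.

## The scoring function

Six restraint classes, each a non-negative term (lower is better), weighted
and summed. `compile_restraints()` precomputes every index structure so one
score evaluation is a handful of vectorized kernel calls (the kernels are in
C++; brute-force R reimplementations back them in the test suite).

**Density (EM) restraint.** The segmented map of each layer is approximated
by an isotropic Gaussian mixture (`fit_gmm_to_map()`, weighted EM over voxel
centers). Model beads of that layer are rendered as Gaussians with
\(\sigma\) = bead radius and mass proportional to residue count; both
mixtures are normalized to unit mass within the layer. For data component
\(k\),
\[ s_k = \tfrac{1}{2\sigma_{em}^2}\,
   \log^2\!\frac{ov_{MD,k}}{ov_{DD,k}}, \]
where \(ov_{MD,k}\) is the model-vs-component overlap and \(ov_{DD,k}\) the
data-vs-component overlap, with the analytic Gaussian overlap integral as the
kernel. A model whose mixture equals the data mixture scores exactly zero;
the lognormal form makes the term monotone in model-map disagreement. The
noise scale `sigma_em` is fixed (default 0.3) rather than marginalized: the
deterministic form is testable and behaves identically in the Metropolis
acceptance ratio. Only beads flagged as density-restrained for the matching
layer contribute; disordered tails and extended chains are excluded, mirroring
how such regions average out of tomogram densities.

**Immuno-EM restraint.** For each record (terminus, antibody-binding residue
range, measured mean and SEM) and each protein copy, the bead in the range
whose \(z\) is closest to the measured mean is scored
\(\frac{1}{2}\left((z^* - \mu)/\text{sem}\right)^2\). The closest-bead rule
reflects that the label could sit anywhere in the antibody-binding region.

**Binding restraint.** A harmonic upper bound on the minimum
surface-to-surface distance between the bead sets of two interacting domains:
zero at or below contact, quadratic above. Copy ambiguity follows the
any-partner rule: for each copy of A the minimum is taken over all beads of
all copies of B (and symmetrically), so several A copies may legitimately
engage the same B copy. Assay classes are weighted overlay = coIP (1.0) >
Y2H = colocalization (0.5); the literature supports only the ordering, the
numbers are package defaults.

**Cylinder restraint.** Mobile beads pay \(k\,\max(0, \rho - R)^2\) outside a
cylinder of radius \(R\) (default 150 A, matching a map-enclosing cylinder;
the toy system uses its own 60 A radius).

**Excluded volume.** Each unordered bead pair overlapping by
\(o = \max(0, r_i + r_j - d)\) pays \(k\,o^2\). Pairs inside one rigid body
(immutable) and consecutive-in-sequence pairs (governed by connectivity) are
exempt.

**Sequence connectivity.** Consecutive beads are restrained by a harmonic
upper bound above a per-pair threshold that interpolates between the globular
limit (sum of radii) and a disordered-chain limit \(c_0 n^\nu\) (defaults
\(c_0 = 1.93\) A, \(\nu = 0.6\), a Flory-type scaling for disordered
regions), mixed by the protein's disorder fraction. The disorder fraction is
an input, not a prediction made by this package. Pairs inside a rigid body
contribute a constant, computed once.

## Sampling

`run_sampling()` performs replica-exchange Gibbs Monte Carlo. One Gibbs sweep
proposes exactly one Metropolis move for every mobile flexible bead
(uniform translation, default max 4 A per axis), every rigid body (random
rotation up to 0.1 rad about a random axis through the body center plus a
translation up to 2 A), and every super-rigid group (all mobile beads of a
protein copy moved together). Acceptance is
\(\min(1, e^{-\Delta S/T})\) on the weighted total score. Replicas follow a
geometric temperature ladder (default 4 replicas, \(T \in [1, 2.5]\));
adjacent pairs attempt configuration swaps after every sweep with alternating
parity and probability
\(\min(1, \exp((1/T_i - 1/T_j)(S_i - S_j)))\). One seeded RNG stream per
replica (derived from the master seed by the documented splitting rule in
`sub_seed()`) makes runs bit-reproducible.

Three constraints are enforced mechanically rather than through the score:

* **Anchoring** — membrane-anchored beads (the transmembrane-adjacent bead of
  a cadherin-like chain) move only in the membrane plane: the \(z\) component
  of any proposed translation is zeroed, and collective moves of groups
  containing an anchored bead are restricted to in-plane translations and
  rotations about the vertical axis. Anchored \(z\) is conserved bit-exactly.
* **Fixed beads** are never proposed.
* **The membrane wall** — proposals taking a mobile bead below \(z = 0\) are
  rejected (a hard wall implemented by rejection keeps the Metropolis kernel
  valid).

Initialization is layer-aware, and uses only quantities derived from the
(simulated) data: lower-layer molecules are placed at molecule-wise density
centroids with random orientations (`initialize_pkp_layer()`); upper-layer
molecules are randomized inside a box around the layer density with a
polarity check — if the rigid body's N-to-C direction along \(z\) contradicts
the terminus-distance data, the body is flipped 180 degrees about a random
in-plane axis (`initialize_pg_layer()`), because a densely packed layer may
not allow polarity reversal during sampling; anchored chains start on the
membrane and walk upward (`initialize_anchored_chain()`).

## Ensemble analysis

The analysis protocol follows the established sampling-exhaustiveness
literature for integrative models:

1. **Equilibration filter.** Per run and replica, a Geweke-style comparison
   (first 10% vs last 50% of the trace, \(|z| < 2\), burn-in grid at 2.5%
   resolution) discards pre-equilibration frames, and the remainder is
   thinned by the integrated autocorrelation time of the total score
   (initial-positive-sequence estimator).
2. **Score-space clustering.** Density-based clustering (DBSCAN-style, with a
   kNN-distance heuristic for the neighborhood radius) of the per-term score
   vectors; the largest cluster is retained, noise allowed.
3. **Good-scoring filter.** Frames whose every per-term score *and* total
   beat the corresponding mean + 1.46 SD are retained. Terms with zero SD are
   compared as \(\le\) mean so perfectly converged terms never discard
   everything.
4. **Exhaustiveness test.** Models are split into two independent halves —
   by run when several independent runs exist (the default, and the more
   stringent test), otherwise by a seeded random split. Scores are compared
   by a two-sample KS test. Structures are compared at each clustering
   threshold: the pooled models are greedily clustered, and the per-cluster
   populations of the halves tested by chi-square with Cramer's V. The
   sampling precision is the smallest threshold with \(p > 0.05\),
   \(V < 0.10\), and at least 80% of models in non-singleton clusters (all
   three thresholds configurable).
5. **Structural clustering.** Greedy centroid clustering at the sampling
   precision using the ambiguity-aware RMSD; the model precision is the mean
   member-to-centroid RMSD of the largest cluster.
6. **Localization densities.** Per-domain voxel maps of the fraction of
   cluster models whose beads intersect each voxel (exact sphere-box test),
   written as MRC.

**Ambiguity.** The RMSD between two models is minimized over bipartite
pairings of equivalent protein copies: per protein, the copy-vs-copy
summed-squared-distance matrix is solved as an assignment problem (an
\(O(n^3)\) Hungarian solver; the test suite checks it against exhaustive
enumeration of all \(n!\) pairings). Proteins containing fixed beads are
matched by copy index instead — immobile fitted copies pin the identity of
their neighbors, which also removes the need for superposition: all models
share the fixed common frame. The package never superposes models.

## The synthetic study system

`generate_toy_assembly()` plants a ground truth emulating the layered
architecture the pipeline targets: a 60 A-radius cylinder with two 40 A
z-bands; an "arm" protein with a structured two-bead core in the lower band
plus a flexible tail penetrating the upper band; a "plak" protein with a
three-bead structured core in the upper band plus an outward flexible tail;
and a membrane-anchored flexible "anc" chain threading both layers. Three
proteins, two copies each, 30 beads.

Four inter-protein domain contacts are planted as *exact surface
tangencies* (anc-arm core, anc-arm tail, anc-plak core, arm tail-plak
core), so the truth simultaneously has zero binding, excluded-volume,
connectivity and cylinder scores. The geometry is constructed so that every
non-planted domain pair is separated by roughly twice the 10 A contact-map
cutoff in the truth: planted and absent contacts are unambiguous by design.
Construction is randomized (global azimuth, body spins, sub-Angstrom waypoint
jitter) and verified against all constraints, with rejection and retry.

Simulated inputs derive from the truth: per-layer density maps (sum of the
restrained beads' Gaussians, rasterized), an immuno-EM table (one record per
terminus, antibody range = the terminal bead, measured mean = across-copy
true \(z\) plus Gaussian noise with SEM 5 A), and a binding table (one record
per planted contact, assay classes cycled). With the antibody range covering
exactly one bead, each per-copy immuno term is \(\tfrac12\) times a squared
standard normal — expectation 0.5 — which the planted-satisfaction tests
check.

What the toy does *not* emulate: realistic tomographic noise (CTF, missing
wedge), heterogeneous copy numbers, crowding by unmodeled species, or
experimentally realistic contact sparsity. Passing the recovery experiment
therefore demonstrates the *pipeline's* correctness — that the restraints,
sampler and analysis protocol jointly recover a known answer from data of the
stated form — not that any particular real assembly is correctly modeled.

## The recovery experiment

`recover_once()` runs the full pipeline on one seed: simulate, fit mixtures,
compile restraints, sample, filter, test exhaustiveness, cluster, call
contacts. The defaults (`recovery_config()`) are 3 independent runs of 4
replicas for 600 sweeps each, a frame every 10 sweeps, mixture size equal to
the number of restrained beads per layer. These sizes were chosen from pilot
convergence diagnostics: score traces equilibrate well within the first
quarter of a run, and two runs proved too few to average over the azimuthal
flank ambiguity of chain-core contacts (a genuine multimodality of the
posterior), while three runs give stable centroids. A full five-seed
experiment runs in minutes on one CPU.

Recovery is scored by three quantities: the ambiguity-aware RMSD from the
major-cluster centroid to the truth (which should fall below the cluster's
model precision — the posterior is centered on the truth within its own
spread), the recall of planted contacts among domain-pair calls at the 25%
contact-frequency threshold, and the number of false domain-pair calls above
that threshold.

## Numerical choices and degenerate cases

* Exact tangency is degenerate under floating point: contact enumeration and
  the satisfied-fraction of `binding_fit()` use a 1e-6 A touch tolerance;
  the harmonic scores themselves need no tolerance (a 1e-16 A overlap
  contributes ~1e-32 score).
* GMM fitting floors component sigmas at half a voxel to prevent collapse,
  and seeds centers by density-weighted k-means++; the fit is deterministic
  given its seed.
* The EM term caps each component's score (default 1e6) when the model
  overlap underflows to zero, keeping the Metropolis ratio finite.
* Zero-variance score terms pass the good-scoring filter by the \(\le\) mean
  rule.
* Greedy clustering breaks ties by frame index; all analysis steps are
  deterministic given their seeds.
* The Geweke burn-in grid stops when fewer than 20 frames remain; traces
  that never equilibrate are excluded with a warning rather than silently
  kept.

## Known limitations

* The EM likelihood is a fixed-noise lognormal overlap score, not a
  marginalized Bayesian treatment of the noise hyperparameters; anisotropic
  components are not supported.
* Scoring is fully recomputed per proposal; incremental delta-scoring would
  be the next optimization for much larger systems.
* The Hungarian-based RMSD is exact but quadratic in ensemble size when a
  full matrix is required; very large ensembles should be subsampled before
  `rmsd_matrix()`.
* Mover step sizes and the temperature ladder are fixed defaults, not
  auto-tuned; systems much larger or stiffer than the toy will need manual
  adjustment.
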