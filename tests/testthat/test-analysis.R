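# ---- equilibration and autocorrelation -------------------------------------

test_that("autocorrelation time recovers the AR(1) closed form and white noise", {
  withr::local_seed(1)
  taus <- replicate(5, autocorrelation_time(rnorm(2000)))
  expect_lt(max(abs(taus - 1)), 0.5)
  phi <- 0.6
  tau_true <- (1 + phi) / (1 - phi)
  est <- replicate(10, {
    x <- as.numeric(arima.sim(list(ar = phi), 5000))
    autocorrelation_time(x)
  })
  expect_equal(mean(est), tau_true, tolerance = 0.2)
})

test_that("burn-in detection finds the planted change point", {
  withr::local_seed(2)
  expect_equal(detect_burn_in(rnorm(400)), 0)
  n <- 400; planted <- 120
  errs <- replicate(100, {
    ramp <- c(seq(40, 0, length.out = planted), rep(0, n - planted))
    b <- detect_burn_in(ramp + rnorm(n))
    abs(b - planted)
  })
  expect_lte(mean(errs), 0.10 * n)
})

test_that("the equilibration filter removes ramps and thins correlated traces", {
  truth <- generate_toy_assembly(seed = 3)
  withr::local_seed(3)
  ens <- perturbed_ensemble(truth, n = 200, sd = 2, n_runs = 2, seed = 4)
  # white-noise totals: burn-in 0, thinning 1 everywhere
  filt <- equilibration_filter(ens)
  info <- attr(filt, "filter_info")
  expect_true(all(vapply(info, `[[`, numeric(1), "burn_in") == 0))
  expect_true(all(vapply(info, `[[`, numeric(1), "thin") <= 2))
  # a decaying ramp on one run is discarded
  ens2 <- ens
  r1 <- which(ens2$meta$run == 1)
  ramp <- c(seq(60, 0, length.out = 30), rep(0, length(r1) - 30))
  ens2$scores$total[r1] <- ens2$scores$total[r1] + ramp
  filt2 <- equilibration_filter(ens2)
  b2 <- attr(filt2, "filter_info")[["1 1"]]["burn_in"]
  expect_gt(b2, 10)
})

# ---- score-space clustering and the good-scoring filter --------------------

test_that("score-space clustering retains the largest planted blob", {
  truth <- generate_toy_assembly(seed = 5)
  ens <- perturbed_ensemble(truth, n = 90, sd = 1, n_runs = 1, seed = 6)
  withr::local_seed(7)
  blob <- function(n, ctr) data.frame(
    em = rnorm(n, ctr, 0.3), immuno_em = rnorm(n, ctr, 0.3),
    binding = rnorm(n, ctr, 0.3), cylinder = rnorm(n, ctr, 0.3),
    excluded_volume = rnorm(n, ctr, 0.3), connectivity = rnorm(n, ctr, 0.3),
    total = rnorm(n, ctr, 0.3))
  ens$scores <- rbind(blob(60, 0), blob(30, 40))
  ens$scores <- ens$scores  # 60-frame blob is the larger
  sub <- score_space_cluster(ens)
  labels <- attr(sub, "labels")
  expect_equal(length(unique(labels[labels > 0])), 2)
  expect_true(all(which(labels == labels[1]) %in% 1:60))
  expect_gte(n_frames(sub), 55)
  # a single tight blob keeps nearly everything
  ens$scores <- blob(90, 0)
  sub2 <- score_space_cluster(ens)
  expect_gte(n_frames(sub2) / 90, 0.95)
  # duplicated ensembles get identical labels for duplicates
  ens3 <- subset_ensemble(ens, c(seq_len(90), seq_len(90)))
  sub3 <- score_space_cluster(ens3)
  l3 <- attr(sub3, "labels")
  expect_equal(l3[1:90], l3[91:180])
})

test_that("the good-scoring filter applies the mean + n_sd rule per term", {
  truth <- generate_toy_assembly(seed = 8)
  ens <- perturbed_ensemble(truth, n = 5, sd = 1, n_runs = 1, seed = 9)
  # identical frames: zero SD, everything retained
  ens$scores <- data.frame(em = rep(1, 5), immuno_em = 1, binding = 1,
                           cylinder = 1, excluded_volume = 1,
                           connectivity = 1, total = 6)
  expect_equal(n_frames(good_scoring_filter(ens)), 5)
  # hand-built table with one outlier in one term
  ens$scores$binding <- c(1, 1, 1, 1, 10)
  ens$scores$total <- rowSums(ens$scores[, 1:6])
  kept <- good_scoring_filter(ens, n_sd = 1.46)
  expect_equal(n_frames(kept), 4)
  # shift invariance: adding a constant to one term changes nothing
  ens2 <- ens
  ens2$scores$em <- ens2$scores$em + 100
  kept2 <- good_scoring_filter(ens2, n_sd = 1.46)
  expect_equal(n_frames(kept2), n_frames(kept))
  # retention is monotone in n_sd
  sizes <- vapply(c(1.0, 1.46, 2.0, 3.0), function(s)
    n_frames(good_scoring_filter(ens, s)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

# ---- assignment and ambiguity-aware RMSD -----------------------------------

test_that("the Hungarian solver matches exhaustive enumeration", {
  withr::local_seed(10)
  perms <- function(n) {
    if (n == 1) return(matrix(1))
    p <- perms(n - 1)
    do.call(rbind, lapply(seq_len(n), function(k)
      cbind(k, ifelse(p >= k, p + 1, p))))
  }
  for (i in 1:40) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n, 0, 100), n)
    asg <- solve_assignment(cost)
    best <- min(apply(perms(n), 1, function(pm)
      sum(cost[cbind(seq_len(n), pm)])))
    expect_equal(sum(cost[cbind(seq_len(n), asg)]), best, tolerance = 1e-12)
  }
})

test_that("ambiguous RMSD is permutation-invariant and matches brute force", {
  topo <- assembly_topology(list(
    protein_spec("p4", aa_seq(60), copies = 4, domains = list(
      domain_spec("d", c(1, 60), "flexible"))),
    protein_spec("q2", aa_seq(40), copies = 2, domains = list(
      domain_spec("d", c(1, 40), "flexible")))))
  rep_ <- build_representation(topo)
  g <- rmsd_grouping(rep_)
  co <- rand_config(rep_, 11)
  expect_equal(ambiguous_rmsd(co, co, g), 0)
  # swapping two copies of one protein still gives zero
  b <- rep_$beads
  co2 <- co
  i1 <- which(b$protein == "p4" & b$copy == 1)
  i3 <- which(b$protein == "p4" & b$copy == 3)
  co2[i1, ] <- co[i3, ]; co2[i3, ] <- co[i1, ]
  expect_equal(ambiguous_rmsd(co, co2, g), 0, tolerance = 1e-12)
  # assignment equals brute force over all 4! x 2! pairings
  for (s in 1:25) {
    ca <- rand_config(rep_, 200 + s)
    cb <- rand_config(rep_, 300 + s)
    expect_equal(ambiguous_rmsd(ca, cb, g), oracle_perm_rmsd(ca, cb, g),
                 tolerance = 1e-12)
  }
  # proteins with fixed beads are matched by copy index
  repf <- build_representation(mini_topology(copies_b = 2, fixed_a = TRUE))
  gf <- rmsd_grouping(repf)
  expect_false(gf[["pa"]]$interchangeable)
})

test_that("ambiguous RMSD is a pseudo-metric on random triples", {
  topo <- assembly_topology(list(
    protein_spec("p", aa_seq(40), copies = 3, domains = list(
      domain_spec("d", c(1, 40), "flexible")))))
  rep_ <- build_representation(topo)
  g <- rmsd_grouping(rep_)
  viol <- 0
  for (s in 1:300) {
    ca <- rand_config(rep_, 3 * s)
    cb <- rand_config(rep_, 3 * s + 1)
    cc <- rand_config(rep_, 3 * s + 2)
    dab <- ambiguous_rmsd(ca, cb, g)
    dba <- ambiguous_rmsd(cb, ca, g)
    expect_equal(dab, dba, tolerance = 1e-12)
    if (dab > ambiguous_rmsd(ca, cc, g) + ambiguous_rmsd(cc, cb, g) + 1e-9)
      viol <- viol + 1
  }
  expect_lte(viol / 300, 0.01)
})

# ---- exhaustiveness and structural clustering ------------------------------

test_that("the exhaustiveness verdict is stable across random half-splits", {
  truth <- generate_toy_assembly(seed = 12)
  ens <- perturbed_ensemble(truth, n = 80, sd = 3, n_runs = 1, seed = 13)
  rmat <- rmsd_matrix(ens)
  passes <- vapply(1:50, function(s)
    exhaustiveness_test(ens, rmsd_mat = rmat, split = "random",
                        seed = s)$pass, logical(1))
  expect_gt(mean(passes), 0.9)
  # duplicating every model does not change the verdict: population
  # proportions (hence Cramer's V) are scale-invariant
  ens2 <- subset_ensemble(ens, rep(seq_len(80), 2))
  rmat2 <- rmsd_matrix(ens2)
  thr <- quantile(rmat[upper.tri(rmat)], c(0.3, 0.5, 0.8), names = FALSE)
  ex1 <- exhaustiveness_test(ens, thresholds = thr, rmsd_mat = rmat,
                             split = "random", seed = 1)
  ex2 <- exhaustiveness_test(ens2, thresholds = thr, rmsd_mat = rmat2,
                             split = "random", seed = 1)
  expect_equal(ex2$pass, ex1$pass)
  expect_true(all(ex2$tests$cramers_v < 0.3))
})

test_that("structural clustering separates planted conformations and measures spread", {
  truth <- generate_toy_assembly(seed = 14)
  # identical frames: one cluster, model precision zero
  ens0 <- perturbed_ensemble(truth, n = 10, sd = 1e-9, n_runs = 1, seed = 15)
  cl0 <- structural_cluster(ens0, threshold = 1)
  expect_equal(length(cl0$sizes), 1)
  expect_equal(cl0$model_precision, 0, tolerance = 1e-6)
  # two basins far beyond the threshold give two clusters
  basin2 <- truth$coords
  basin2[, 1] <- basin2[, 1] + 120
  ens2 <- perturbed_ensemble(truth, n = 60, sd = 2, n_runs = 2,
                             second_basin = basin2, seed = 16)
  rmat2 <- rmsd_matrix(ens2)
  cl2 <- structural_cluster(ens2, threshold = 15, rmsd_mat = rmat2)
  expect_equal(length(cl2$sizes), 2)
  # model precision of an isotropic Gaussian cloud matches the Maxwell mean
  topo1 <- assembly_topology(list(
    protein_spec("s", aa_seq(20), domains = list(
      domain_spec("d", c(1, 20), "flexible")))))
  rep1 <- build_representation(topo1)
  sigma <- 2
  withr::local_seed(17)
  frames <- lapply(1:400, function(i) matrix(rnorm(3, 0, sigma), 1))
  ens1 <- ensemble(frames,
                   data.frame(em = 0, immuno_em = 0, binding = 0,
                              cylinder = 0, excluded_volume = 0,
                              connectivity = 0, total = rnorm(400)),
                   data.frame(run = 1, replica = 1, sweep = 1:400,
                              temperature = 1), rep1)
  cl1 <- structural_cluster(ens1, threshold = 1e6)
  expect_equal(cl1$model_precision, sigma * sqrt(8 / pi), tolerance = 0.1)
})

test_that("localization densities are occupancy fractions on the voxel grid", {
  rep_ <- build_representation(mini_topology(copies_b = 1, fixed_a = TRUE))
  b <- rep_$beads
  base <- rep_$coords
  base[is.na(base)] <- 0
  flex <- which(b$mobile)
  base[flex, ] <- cbind(30 + 6 * seq_along(flex), 0, 10)
  # bead of pb copy 1 alternates between two sites across 10 frames
  frames <- lapply(1:10, function(f) {
    co <- base
    if (f <= 5) co[flex[1], ] <- c(-30, 0, 10) else co[flex[1], ] <- c(-30, 0, 40)
    co
  })
  ens <- ensemble(frames, data.frame(em = 0, immuno_em = 0, binding = 0,
                                     cylinder = 0, excluded_volume = 0,
                                     connectivity = 0, total = 0)[rep(1, 10), ],
                  data.frame(run = 1, replica = 1, sweep = 1:10,
                             temperature = 1), rep_)
  # fixed protein: value 1 inside its beads, 0 elsewhere
  ld_fixed <- localization_density(ens, "pa", voxel = 4)
  expect_true(all(ld_fixed$data %in% c(0, 1)))
  expect_gt(sum(ld_fixed$data == 1), 0)
  # alternating bead: its two sites have value 0.5
  ld <- localization_density(ens, "pb", voxel = 4)
  expect_true(all(ld$data >= 0 & ld$data <= 1))
  ctr_val <- ld$data[
    round((-30 - ld$origin[1]) / ld$voxel) + 1,
    round((0 - ld$origin[2]) / ld$voxel) + 1,
    round((10 - ld$origin[3]) / ld$voxel) + 1]
  expect_equal(ctr_val, 0.5)
  # duplication invariance
  ld2 <- localization_density(subset_ensemble(ens, rep(1:10, 2)), "pb",
                              voxel = 4)
  expect_equal(ld2$data, ld$data)
})
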