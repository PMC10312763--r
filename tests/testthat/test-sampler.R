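test_that("anchoring projects proposed translations onto the membrane plane", {
  expect_equal(apply_anchoring(c(1, 2, 3), TRUE), c(1, 2, 0))
  expect_equal(apply_anchoring(c(1, 2, 3), FALSE), c(1, 2, 3))
})

test_that("Metropolis sweeps accept everything at infinite temperature and all downhill moves", {
  rep_ <- one_bead_rep()
  plan <- score_plan(rep_, function(co) 0.1 * sum(co^2))
  st <- list(coords = matrix(c(0, 0, 0), 1), terms = c(custom = 0))
  withr::local_seed(1)
  # flat score: every proposal accepted
  flat <- score_plan(rep_, function(co) 0)
  acc <- 0
  for (i in 1:50) {
    st2 <- gibbs_sweep(st, flat, mover_set(), temperature = 1)
    acc <- acc + st2$accepted
  }
  expect_equal(acc, 50)
  # downhill moves always accepted even at tiny temperature
  st <- list(coords = matrix(c(100, 0, 0), 1),
             terms = c(custom = plan$score(matrix(c(100, 0, 0), 1))))
  down <- 0; tried <- 0
  for (i in 1:200) {
    old <- st$coords[1, 1]
    st <- gibbs_sweep(st, plan, mover_set(bead_step = 1), temperature = 1e-9)
    if (st$coords[1, 1] < old - 1e-12) down <- down + 1
    tried <- tried + 1
  }
  expect_gt(down / tried, 0.3)     # roughly half of proposals are downhill
  expect_lt(st$coords[1, 1], 100)  # net descent
})

test_that("a single bead in a harmonic well reproduces the Boltzmann variance", {
  rep_ <- one_bead_rep()
  k <- 0.02
  plan <- score_plan(rep_, function(co) 0.5 * k * co[1, 1]^2)
  st <- list(coords = matrix(c(0, 0, 0), 1), terms = c(custom = 0))
  xs <- numeric(20000)
  withr::local_seed(7)
  for (i in seq_along(xs)) {
    st <- gibbs_sweep(st, plan, mover_set(bead_step = 8), temperature = 1)
    xs[i] <- st$coords[1, 1]
  }
  xs <- xs[-(1:2000)]
  expect_equal(var(xs), 1 / k, tolerance = 0.08)
})

test_that("two-bead harmonic pair distance follows the closed-form Boltzmann law", {
  topo <- assembly_topology(list(
    protein_spec("p1", aa_seq(20), domains = list(
      domain_spec("d", c(1, 20), "flexible"))),
    protein_spec("p2", aa_seq(20), domains = list(
      domain_spec("d", c(1, 20), "flexible")))))
  rep_ <- build_representation(topo)
  k <- 0.05
  plan <- score_plan(rep_, function(co)
    0.5 * k * sum((co[1, ] - co[2, ])^2))
  st <- list(coords = rbind(c(0, 0, 0), c(5, 0, 0)), terms = c(custom = 0))
  st$terms <- plan$score(st$coords)
  n <- 30000
  dists <- numeric(n)
  withr::local_seed(11)
  for (i in seq_len(n)) {
    st <- gibbs_sweep(st, plan, mover_set(bead_step = 6), temperature = 1)
    dists[i] <- sqrt(sum((st$coords[1, ] - st$coords[2, ])^2))
  }
  dists <- dists[-(1:3000)]
  thin <- max(1, ceiling(autocorrelation_time(dists)))
  sub <- dists[seq(1, length(dists), by = thin)]
  # the pair potential couples only the relative coordinate, which is
  # isotropic Gaussian with per-axis variance T/k; the distance is then
  # Maxwell-Boltzmann with scale sqrt(T/k)
  scale <- sqrt(1 / k)
  pmaxwell <- function(q) {
    x <- q / scale
    2 * pnorm(x) - 1 - sqrt(2 / pi) * x * exp(-x^2 / 2)
  }
  ks <- suppressWarnings(ks.test(sub, pmaxwell))
  expect_gt(ks$p.value, 0.01)
})

test_that("replica exchange swaps with the prescribed probability", {
  mk <- function(total) list(coords = matrix(0, 1, 3),
                             terms = c(custom = total), total = total)
  withr::local_seed(3)
  # equal temperatures: always swap
  r <- list(mk(10), mk(50))
  sw <- 0
  for (i in 1:100) {
    ex <- replica_exchange_step(r, c(1, 1), parity = 0)
    sw <- sw + ex$swaps
  }
  expect_equal(sw, 100)
  # identical scores: always swap
  r <- list(mk(7), mk(7))
  ex <- replica_exchange_step(r, c(1, 2), parity = 0)
  expect_equal(ex$swaps, 1)
  # uphill-in-beta swaps happen at rate exp((b1-b2)(S1-S2))
  p_theory <- exp((1 - 1 / 2) * (10 - 20))
  hits <- 0
  for (i in 1:4000) {
    ex <- replica_exchange_step(list(mk(10), mk(20)), c(1, 2), parity = 0)
    hits <- hits + ex$swaps
  }
  expect_equal(hits / 4000, p_theory, tolerance = 0.4)
})

test_that("fixed and anchored coordinates are conserved bit-exactly; rigid bodies stay rigid", {
  rep_ <- build_representation(mini_topology(copies_b = 2, fixed_a = TRUE))
  b <- rep_$beads
  plan <- score_plan(rep_, function(co) 0.001 * sum(co[, 3]^2),
                     positive_z = TRUE)
  init <- function(r, seed) {
    co <- r$coords
    flex <- which(b$mobile)
    co[flex, ] <- cbind(runif(length(flex), -20, 20),
                        runif(length(flex), -20, 20),
                        runif(length(flex), 5, 40))
    co[b$anchored, 3] <- 0
    co
  }
  ens <- run_sampling(plan, init, movers = mover_set(),
                      ladder = replica_ladder(2, t_max = 2),
                      run = sampling_run(60, save_period = 10),
                      n_runs = 1, seed = 5)
  fixed <- which(!b$mobile)
  anchored <- which(b$anchored)
  ref <- ens$frames[[1]]
  for (f in ens$frames) {
    expect_identical(f[fixed, ], ref[fixed, ])
    expect_identical(f[anchored, 3], ref[anchored, 3])
  }
  # mobile beads did move
  expect_gt(max(abs(ens$frames[[length(ens$frames)]][b$mobile, ] -
                      ens$frames[[1]][b$mobile, ])), 0.1)

  # rigid-body interior: sample a mobile body and check distance drift
  rep2 <- mini_rep(copies_b = 1)
  plan2 <- score_plan(rep2, function(co) 0.001 * sum(co^2))
  init2 <- function(r, seed) {
    co <- r$coords
    co[is.na(co)] <- 0
    co
  }
  ens2 <- run_sampling(plan2, init2, run = sampling_run(100, 20),
                       ladder = replica_ladder(1), seed = 9)
  body <- rep2$rigid_bodies[[1]]
  d0 <- dist(rep2$coords[body, ])
  for (f in ens2$frames)
    expect_lt(max(abs(dist(f[body, ]) - d0)), 1e-6)
})

test_that("sampling runs are seed-reproducible with the expected frame count", {
  rep_ <- one_bead_rep()
  plan <- score_plan(rep_, function(co) 0.01 * sum(co^2))
  init <- function(r, seed) matrix(runif(3, -10, 10), 1)
  e1 <- run_sampling(plan, init, ladder = replica_ladder(2, t_max = 2),
                     run = sampling_run(100, save_period = 10),
                     n_runs = 2, seed = 42)
  e2 <- run_sampling(plan, init, ladder = replica_ladder(2, t_max = 2),
                     run = sampling_run(100, save_period = 10),
                     n_runs = 2, seed = 42)
  # 100 sweeps / save 10 = 10 frames x 2 replicas x 2 runs
  expect_equal(n_frames(e1), 40)
  expect_identical(e1$frames, e2$frames)
  expect_equal(e1$scores, e2$scores)
  e3 <- run_sampling(plan, init, ladder = replica_ladder(2, t_max = 2),
                     run = sampling_run(100, save_period = 10),
                     n_runs = 2, seed = 43)
  expect_false(identical(e1$frames, e3$frames))
})

test_that("total score decreases in distribution from initialization to equilibrium", {
  rep_ <- mini_rep(copies_b = 2)
  plan <- mini_plan(rep_)
  init <- function(r, seed) {
    co <- r$coords
    flex <- which(is.na(co[, 1]))
    co[flex, ] <- cbind(runif(length(flex), -45, 45),
                        runif(length(flex), -45, 45),
                        runif(length(flex), 0, 60))
    co[r$beads$anchored, 3] <- 0
    co
  }
  firsts <- lasts <- numeric(6)
  for (s in 1:6) {
    ens <- run_sampling(plan, init, ladder = replica_ladder(1),
                        run = sampling_run(150, save_period = 5),
                        n_runs = 1, seed = 100 + s)
    tr <- ens$scores$total
    firsts[s] <- median(tr[seq_len(3)])
    lasts[s] <- median(tr[(length(tr) - 2):length(tr)])
  }
  expect_lt(median(lasts), median(firsts))
})

test_that("upper-layer initialization randomizes in the box and honors polarity", {
  rep_ <- mini_rep(copies_b = 1)
  box <- list(min = c(-40, -40, 30), max = c(40, 40, 90))
  body <- rep_$rigid_bodies[[1]]
  b <- rep_$beads
  o <- order(b$res_start[body])
  flips <- 0
  withr::local_seed(21)
  for (i in 1:300) {
    co <- initialize_pg_layer(rep_, rep_$coords, "pa", box,
                              polarity = c(pa = "N"))
    placed <- co[body, ]
    # all body beads inside the box (up to the body extent)
    ctr <- colMeans(placed)
    expect_true(all(ctr >= box$min & ctr <= box$max))
    # polarity: N-end bead strictly below C-end bead
    expect_lt(placed[o[1], 3], placed[o[length(o)], 3])
  }
  # flipping occurs: with C-proximal polarity the sign reverses
  co2 <- initialize_pg_layer(rep_, rep_$coords, "pa", box,
                             polarity = c(pa = "C"))
  placed2 <- co2[body, ]
  expect_gt(placed2[o[1], 3], placed2[o[length(o)], 3])
  # box smaller than the body errors
  tiny <- list(min = c(0, 0, 0), max = c(5, 5, 5))
  expect_error(initialize_pg_layer(rep_, rep_$coords, "pa", tiny,
                                   polarity = c(pa = "N")), "too small")
})

test_that("lower-layer initialization assigns copies to molecule densities 1:1", {
  topo <- assembly_topology(list(
    protein_spec("pk", aa_seq(60), copies = 3, domains = list(
      domain_spec("core", c(1, 60), "rigid",
                  structure_source = line_coords(60))))))
  rep_ <- build_representation(topo)
  cen <- rbind(c(-30, 0, 20), c(0, 30, 20), c(30, 0, 20))
  withr::local_seed(31)
  co <- initialize_pkp_layer(rep_, rep_$coords, "pk", cen)
  b <- rep_$beads
  used <- integer(3)
  for (cp in 1:3) {
    ctr <- colMeans(co[b$copy == cp, , drop = FALSE])
    d <- sqrt(rowSums(sweep(cen, 2, ctr)^2))
    expect_lt(min(d), 15)          # centered at its assigned density
    used[which.min(d)] <- used[which.min(d)] + 1L
  }
  expect_equal(used, rep(1L, 3))   # a bijection, no density shared
  expect_error(initialize_pkp_layer(rep_, rep_$coords, "pk",
                                    cen[1:2, , drop = FALSE]), "fewer")
})
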