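make_two_beads <- function(r = 10) {
  topo <- assembly_topology(list(
    protein_spec("p", aa_seq(40), copies = 1,
                 domains = list(domain_spec("d", c(1, 40), "flexible")))))
  build_representation(topo)
}

test_that("excluded volume penalizes overlap quadratically", {
  rep_ <- mini_rep(copies_b = 1)
  plan <- compile_restraints(rep_, restraint_set(excluded_volume_restraint()))
  co <- rand_config(rep_, 1, spread = 200)     # sparse: no overlaps
  expect_equal(plan$score(co)[["excluded_volume"]], 0)
  # two beads of radius 10 at distance 15: overlap 5, score k * 25
  topo <- assembly_topology(list(
    protein_spec("q1", aa_seq(20), domains = list(
      domain_spec("d", c(1, 20), "flexible"))),
    protein_spec("q2", aa_seq(20), domains = list(
      domain_spec("d", c(1, 20), "flexible")))))
  r2 <- build_representation(topo)
  r2$beads$radius <- c(10, 10)
  p2 <- compile_restraints(r2, restraint_set(excluded_volume_restraint(k = 2)))
  co2 <- rbind(c(0, 0, 0), c(15, 0, 0))
  expect_equal(p2$score(co2)[["excluded_volume"]], 2 * 25)
})

test_that("cylinder restraint is a harmonic wall with axial symmetry", {
  rep_ <- make_two_beads()
  plan <- compile_restraints(rep_, restraint_set(cylinder_restraint(150)))
  co <- rbind(c(100, 0, 5), c(0, -149, 50))
  expect_equal(plan$score(co)[["cylinder"]], 0)
  co2 <- rbind(c(160, 0, 5), c(0, 0, 50))
  expect_equal(plan$score(co2)[["cylinder"]], 100)
  # invariant under rotation about z
  R <- desmodel:::rotation_about_axis(c(0, 0, 1), 1.234)
  expect_equal(plan$score(co2 %*% t(R))[["cylinder"]],
               plan$score(co2)[["cylinder"]])
})

test_that("connectivity penalizes only super-threshold gaps; rigid interior is constant", {
  rep_ <- make_two_beads()
  plan <- compile_restraints(rep_, restraint_set(connectivity_restraint()))
  thr <- plan$conn$thr[1]
  co <- rbind(c(0, 0, 0), c(thr - 1, 0, 0))
  expect_equal(plan$score(co)[["connectivity"]], 0)
  co2 <- rbind(c(0, 0, 0), c(thr + 4, 0, 0))
  expect_equal(plan$score(co2)[["connectivity"]], 16)

  # moving a rigid body rigidly never changes its internal contribution:
  # the intra-body pairs' score is identical at any posed configuration
  repr <- mini_rep(copies_b = 1)
  cp_tab <- consecutive_pairs(repr)
  intra <- cp_tab[cp_tab$intra_body, ]
  co_a <- rand_config(repr, 5)
  body <- repr$rigid_bodies[[1]]
  co_b <- co_a
  R <- desmodel:::rotation_about_axis(c(1, 1, 0), 0.9)
  ctr <- colMeans(co_a[body, ])
  co_b[body, ] <- sweep(sweep(co_a[body, , drop = FALSE], 2, ctr) %*% t(R),
                        2, ctr + c(3, 4, 5), "+")
  expect_equal(oracle_conn(co_b, intra$i, intra$j, intra$threshold),
               oracle_conn(co_a, intra$i, intra$j, intra$threshold),
               tolerance = 1e-9)
})

test_that("immuno-EM restraint scores the closest bead per copy", {
  rep_ <- mini_rep(copies_b = 2)
  rec <- data.frame(protein = "pb", terminus = "C", res_start = 21,
                    res_end = 40, mean_distance = 30, sem = 5)
  plan <- compile_restraints(rep_, restraint_set(immuno_em_restraint(rec)))
  co <- rand_config(rep_, 3)
  in_range <- which(rep_$beads$protein == "pb" & rep_$beads$res_start >= 21)
  co[in_range, 3] <- 30                       # every candidate at the mean
  expect_equal(plan$score(co)[["immuno_em"]], 0)
  co[in_range, 3] <- 35                       # all at mean + sem
  expect_equal(plan$score(co)[["immuno_em"]], 0.5 * 2)  # two copies
  # closest-bead rule: one bead at mean + 5, another at mean + 10 per copy
  for (cp in 1:2) {
    ix <- in_range[rep_$beads$copy[in_range] == cp]
    co[ix[1], 3] <- 35; co[ix[2], 3] <- 40
  }
  expect_equal(plan$score(co)[["immuno_em"]], 0.5 * 2)
  # record that maps to no bead errors
  bad <- rec; bad$protein <- "nope"
  expect_error(compile_restraints(rep_, restraint_set(immuno_em_restraint(bad))),
               "no bead")
})

test_that("binding restraint uses the min-pair rule with copy ambiguity", {
  rep_ <- mini_rep(copies_b = 2)
  b <- rep_$beads
  rec <- data.frame(protein_a = "pa", res_start_a = 1, res_end_a = 60,
                    protein_b = "pb", res_start_b = 1, res_end_b = 40,
                    assay = "overlay")
  plan <- compile_restraints(rep_, restraint_set(binding_restraint(rec)))
  ia <- which(b$protein == "pa"); ib <- which(b$protein == "pb")
  co <- rand_config(rep_, 4, spread = 300)
  # plant a touching pair for every copy: score 0
  co[ia, ] <- matrix(c(0, 0, 50, 0, 0, 70), 2, byrow = TRUE)
  r_pa <- b$radius[ia[1]]; r_pb <- b$radius[ib[1]]
  for (cp in 1:2) {
    ix <- ib[b$copy[ib] == cp]
    co[ix[1], ] <- c(r_pa + r_pb, 0, 50)       # tangent to pa bead 1
    co[ix[2], ] <- c(200, 200 + 100 * cp, 200)
  }
  expect_equal(plan$score(co)[["binding"]], 0)
  # both B copies bound to the same A bead is allowed (score 0)
  ix2 <- ib[b$copy[ib] == 2]
  co[ix2[1], ] <- c(-r_pa - r_pb, 0, 50)
  expect_equal(plan$score(co)[["binding"]], 0)

  # single-copy proteins at separation d0: score = weight * k * d0^2
  rep1 <- mini_rep(copies_b = 1)
  b1 <- rep1$beads
  rec$assay <- "Y2H"                           # weight 0.5
  p1 <- compile_restraints(rep1, restraint_set(binding_restraint(rec, k = 2)))
  co1 <- rand_config(rep1, 5, spread = 500)
  ia1 <- which(b1$protein == "pa"); ib1 <- which(b1$protein == "pb")
  co1[ia1, ] <- matrix(c(0, 0, 10, 0, 0, 30), 2, byrow = TRUE)
  co1[ib1, ] <- matrix(c(1000, 0, 10, 1200, 0, 10), 2, byrow = TRUE)
  # min surface distance computed by the oracle
  d0 <- oracle_min_surface(co1, b1$radius, ia1, ib1)
  expect_equal(p1$score(co1)[["binding"]], 2 * 0.5 * 2 * d0^2)

  # min-rule dominance: the ambiguous score never exceeds the score of any
  # fixed bipartite assignment of copies (here: both proteins single-domain,
  # so a fixed assignment restricts each copy to its assigned partner)
  topo2 <- assembly_topology(list(
    protein_spec("pa", aa_seq(40), copies = 2, domains = list(
      domain_spec("d", c(1, 40), "flexible"))),
    protein_spec("pb", aa_seq(40), copies = 2, domains = list(
      domain_spec("d", c(1, 40), "flexible")))))
  rep2 <- build_representation(topo2)
  b2 <- rep2$beads
  p2 <- compile_restraints(rep2, restraint_set(
    binding_restraint(data.frame(protein_a = "pa", res_start_a = 1,
                                 res_end_a = 40, protein_b = "pb",
                                 res_start_b = 1, res_end_b = 40,
                                 assay = "overlay"))))
  idx <- function(p, cp) which(b2$protein == p & b2$copy == cp)
  for (s in 1:20) {
    co2 <- rand_config(rep2, 100 + s, spread = 60)
    amb <- p2$score(co2)[["binding"]]
    for (perm in list(c(1, 2), c(2, 1))) {
      fixed <- 0
      for (cp in 1:2) {
        da <- oracle_min_surface(co2, b2$radius, idx("pa", cp),
                                 idx("pb", perm[cp]))
        db <- oracle_min_surface(co2, b2$radius, idx("pb", perm[cp]),
                                 idx("pa", cp))
        fixed <- fixed + max(0, da)^2 + max(0, db)^2
      }
      expect_lte(amb, fixed + 1e-12)
    }
  }
})

test_that("EM restraint is zero at the data mixture and grows along a translation ray", {
  rep_ <- mini_rep(copies_b = 1)
  b <- rep_$beads
  em_idx <- which(b$em_restrained)
  co <- rand_config(rep_, 6)
  # data mixture constructed from the model beads themselves
  bw <- b$n_res[em_idx] / sum(b$n_res[em_idx])
  gmm <- gaussian_mixture(bw, co[em_idx, 1], co[em_idx, 2], co[em_idx, 3],
                          sigma = b$radius[em_idx])
  plan <- compile_restraints(rep_, restraint_set(em_restraint(gmm, "L")))
  expect_equal(plan$score(co)[["em"]], 0, tolerance = 1e-12)
  # translating restrained beads away strictly increases the score
  scores <- vapply(c(0, 2, 5, 10, 20, 40), function(dx) {
    co2 <- co; co2[em_idx, 1] <- co2[em_idx, 1] + dx
    plan$score(co2)[["em"]]
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  # moving non-restrained beads leaves the score unchanged
  co3 <- co
  co3[-em_idx, ] <- co3[-em_idx, ] + 37
  expect_equal(plan$score(co3)[["em"]], plan$score(co)[["em"]])
  # far displacement hits the configured cap
  co4 <- co; co4[em_idx, ] <- co4[em_idx, ] + 1e6
  plan_cap <- compile_restraints(rep_, restraint_set(
    em_restraint(gmm, "L", cap = 123)))
  expect_equal(plan_cap$score(co4)[["em"]], 123 * nrow(gmm$components))
})

test_that("total score is the weighted sum of reported terms", {
  rep_ <- mini_rep()
  plan <- mini_plan(rep_)
  co <- rand_config(rep_, 7)
  rp <- total_score(co, plan)
  expect_true(all(rp$terms >= 0))
  expect_equal(rp$total, sum(rp$weights * rp$terms))
  # doubling one restraint weight changes the total by that term's value
  plan2 <- plan
  plan2$weights["cylinder"] <- 2
  expect_equal(total_score(co, plan2)$total, rp$total + rp$terms[["cylinder"]])
  # all-zero configuration: a sparse, in-cylinder, connected, on-target setup
  expect_equal(sum(total_score(co, plan)$terms < 0), 0)
})

test_that("em, excluded volume and cylinder are invariant under copy relabeling", {
  rep_ <- mini_rep(copies_b = 2)
  plan <- mini_plan(rep_)
  b <- rep_$beads
  co <- rand_config(rep_, 8)
  co2 <- co
  c1 <- which(b$protein == "pb" & b$copy == 1)
  c2 <- which(b$protein == "pb" & b$copy == 2)
  co2[c1, ] <- co[c2, ]; co2[c2, ] <- co[c1, ]
  s1 <- plan$score(co); s2 <- plan$score(co2)
  for (term in c("em", "excluded_volume", "cylinder", "binding", "immuno_em"))
    expect_equal(s2[[term]], s1[[term]], tolerance = 1e-12)
})

test_that("immuno-EM and binding CSV round-trips validate their headers", {
  imm <- data.frame(protein = "pa", terminus = "N", res_start = 1,
                    res_end = 30, mean_distance = 12.5, sem = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(imm, f, row.names = FALSE)
  expect_equal(read_immuno_em_csv(f), imm)
  bad <- imm; bad$sem <- 0
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_immuno_em_csv(f), "sem")
  bnd <- data.frame(protein_a = "pa", res_start_a = 1, res_end_a = 60,
                    protein_b = "pb", res_start_b = 1, res_end_b = 40,
                    assay = "coIP")
  write.csv(bnd, f, row.names = FALSE)
  expect_equal(read_binding_csv(f), bnd)
  write.csv(bnd[, -7], f, row.names = FALSE)
  expect_error(read_binding_csv(f), "columns")
})
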