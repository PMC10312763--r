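#' Monte Carlo mover parameters
#'
#' Maximum move sizes for the three mover classes: individual flexible-bead
#' translations, rigid-body rotation + translation, and super-rigid-body moves
#' (all mobile beads of one protein copy moved together).
#'
#' @param bead_step max per-axis bead translation (A).
#' @param rb_step,rb_angle rigid-body max translation (A) and rotation (rad).
#' @param srb_step,srb_angle super-rigid-body max translation and rotation.
#' @export
mover_set <- function(bead_step = 4, rb_step = 2, rb_angle = 0.1,
                      srb_step = 2, srb_angle = 0.1) {
  stopifnot(bead_step > 0, rb_step > 0, rb_angle > 0, srb_step > 0,
            srb_angle > 0)
  structure(list(bead_step = bead_step, rb_step = rb_step, rb_angle = rb_angle,
                 srb_step = srb_step, srb_angle = srb_angle),
            class = "mover_set")
}

#' Replica-exchange temperature ladder
#'
#' Geometrically spaced temperatures from \code{t_min} to \code{t_max}.
#'
#' @param n_replicas number of replicas.
#' @param t_min,t_max temperature range (t_min = 1 samples the target).
#' @export
replica_ladder <- function(n_replicas = 4, t_min = 1, t_max = 2.5) {
  stopifnot(n_replicas >= 1, t_min > 0, t_max >= t_min)
  temps <- if (n_replicas == 1) t_min else
    t_min * (t_max / t_min)^((seq_len(n_replicas) - 1) / (n_replicas - 1))
  structure(list(n_replicas = n_replicas, temperatures = temps),
            class = "replica_ladder")
}

#' Sampling-run configuration
#' @param n_sweeps Gibbs sweeps per replica.
#' @param save_period save a frame every this many sweeps (default 10).
#' @export
sampling_run <- function(n_sweeps, save_period = 10) {
  stopifnot(n_sweeps >= 1, save_period >= 1)
  structure(list(n_sweeps = as.integer(n_sweeps),
                 save_period = as.integer(save_period)),
            class = "sampling_run")
}

#' Apply the membrane anchoring constraint to a proposed translation
#'
#' Anchored beads move only in the membrane plane: the z component of any
#' proposed translation is zeroed, so their z stays at its initialization
#' value for the whole run. Non-anchored beads are unaffected.
#'
#' @param move length-3 proposed translation.
#' @param anchored logical.
#' @return The (possibly projected) translation.
#' @export
apply_anchoring <- function(move, anchored) {
  if (anchored) move[3] <- 0
  move
}

#' Build the per-sweep proposal schedule for a representation
#'
#' Every mobile flexible bead, every mobile rigid body, and every
#' super-rigid-body group (mobile beads of one protein copy) receives exactly
#' one proposal per sweep. Fixed beads are never proposed.
#' @noRd
build_schedule <- function(rep) {
  b <- rep$beads
  sched <- list()
  free_beads <- which(b$mobile & is.na(b$rigid_body))
  for (i in free_beads)
    sched[[length(sched) + 1L]] <- list(type = "bead", idx = i,
                                        anchored = b$anchored[i])
  for (body in rep$rigid_bodies) {
    if (!all(b$mobile[body])) next
    sched[[length(sched) + 1L]] <- list(type = "body", idx = body,
                                        anchored = any(b$anchored[body]))
  }
  for (p in rep$topology$proteins) for (cp in seq_len(p$copies)) {
    idx <- which(b$protein == p$name & b$copy == cp & b$mobile)
    if (length(idx) < 2) next
    sched[[length(sched) + 1L]] <- list(type = "super", idx = idx,
                                        anchored = any(b$anchored[idx]))
  }
  sched
}

#' Propose a move for one schedule entry; returns updated coords or NULL
#' @noRd
propose_move <- function(coords, entry, movers, positive_z) {
  idx <- entry$idx
  if (entry$type == "bead") {
    tr <- apply_anchoring(runif(3, -movers$bead_step, movers$bead_step),
                          entry$anchored)
    new <- coords[idx, ] + tr
    if (positive_z && !entry$anchored && new[3] < 0) return(NULL)
    coords[idx, ] <- new
    return(coords)
  }
  step <- if (entry$type == "body") movers$rb_step else movers$srb_step
  ang <- if (entry$type == "body") movers$rb_angle else movers$srb_angle
  ctr <- colMeans(coords[idx, , drop = FALSE])
  theta <- runif(1, -ang, ang)
  if (entry$anchored) {
    # groups holding an anchored bead stay in-plane: rotate about the
    # vertical axis, translate in the membrane plane
    R <- rotation_about_axis(c(0, 0, 1), theta)
    tr <- c(runif(2, -step, step), 0)
  } else {
    axis <- rnorm(3)
    while (sum(axis^2) < 1e-12) axis <- rnorm(3)
    R <- rotation_about_axis(axis, theta)
    tr <- runif(3, -step, step)
  }
  block <- sweep(coords[idx, , drop = FALSE], 2, ctr)
  block <- block %*% t(R)
  block <- sweep(block, 2, ctr + tr, "+")
  if (positive_z && any(block[, 3] < 0)) return(NULL)
  coords[idx, ] <- block
  coords
}

#' One Gibbs sweep of Metropolis moves
#'
#' Proposes one move for every mobile bead, rigid body and super-rigid body
#' (in schedule order), accepting with probability
#' \eqn{\min(1, \exp(-\Delta S / T))} on the weighted total score. Proposals
#' that take a mobile bead below the membrane plane, or that produce a
#' non-finite score, are rejected.
#'
#' @param state list with \code{coords} and \code{terms} (current scores).
#' @param plan a compiled \code{restraint_plan}.
#' @param movers a \code{\link{mover_set}}.
#' @param temperature sampling temperature.
#' @param schedule proposal schedule (built from the plan's representation if
#'   omitted).
#' @return Updated state; \code{$accepted} and \code{$proposed} hold
#'   per-sweep acceptance counts.
#' @export
gibbs_sweep <- function(state, plan, movers, temperature, schedule = NULL) {
  if (is.null(schedule)) schedule <- build_schedule(plan$rep)
  coords <- state$coords
  terms <- state$terms
  total <- sum(plan$weights * terms)
  acc <- 0L
  for (entry in schedule) {
    cand <- propose_move(coords, entry, movers, plan$enforce_positive_z)
    if (is.null(cand)) next
    new_terms <- plan$score(cand)
    new_total <- sum(plan$weights * new_terms)
    if (!is.finite(new_total)) next
    d <- new_total - total
    if (d <= 0 || runif(1) < exp(-d / temperature)) {
      coords <- cand; terms <- new_terms; total <- new_total
      acc <- acc + 1L
    }
  }
  list(coords = coords, terms = terms, total = total,
       accepted = acc, proposed = length(schedule))
}

#' One replica-exchange attempt over adjacent pairs
#'
#' Adjacent-temperature pairs of the given parity attempt swaps with
#' probability \eqn{\min(1, \exp((1/T_i - 1/T_j)(S_i - S_j)))}; a swap
#' exchanges configurations (and their scores), not temperatures.
#'
#' @param replicas list of replica states (coords, terms, total).
#' @param temperatures temperature per replica slot.
#' @param parity 0 or 1: attempt pairs (1,2),(3,4),... or (2,3),(4,5),...
#' @return list(replicas, attempts, swaps).
#' @export
replica_exchange_step <- function(replicas, temperatures, parity = 0) {
  n <- length(replicas)
  attempts <- 0L; swaps <- 0L
  first <- 1L + (parity %% 2L)
  ii <- if (first > n - 1L) integer(0) else seq(first, n - 1L, by = 2L)
  for (i in ii) {
    j <- i + 1L
    attempts <- attempts + 1L
    lp <- (1 / temperatures[i] - 1 / temperatures[j]) *
      (replicas[[i]]$total - replicas[[j]]$total)
    if (lp >= 0 || runif(1) < exp(lp)) {
      tmp <- replicas[[i]]; replicas[[i]] <- replicas[[j]]; replicas[[j]] <- tmp
      swaps <- swaps + 1L
    }
  }
  list(replicas = replicas, attempts = attempts, swaps = swaps)
}

#' Run replica-exchange Gibbs Monte Carlo sampling
#'
#' Runs \code{n_runs} independent repeats (differing only by seed) of
#' replica-exchange Gibbs sampling. Each run initializes every replica with
#' \code{init_fn}, performs \code{run$n_sweeps} sweeps with an exchange
#' attempt (alternating parity) after every sweep, and saves a frame from
#' every replica each \code{save_period} sweeps. Per-replica RNG streams are
#' derived from \code{seed} by \code{\link{sub_seed}}.
#'
#' @param plan compiled \code{restraint_plan}.
#' @param init_fn function(rep, seed) returning an N x 3 coordinate matrix.
#' @param movers a \code{\link{mover_set}}.
#' @param ladder a \code{\link{replica_ladder}}.
#' @param run a \code{\link{sampling_run}}.
#' @param n_runs number of independent runs.
#' @param seed master seed.
#' @param progress print a line per run.
#' @return An \code{\link{ensemble}} with per-frame scores and provenance
#'   (run, replica slot, sweep, temperature) plus acceptance statistics.
#' @export
run_sampling <- function(plan, init_fn, movers = mover_set(),
                         ladder = replica_ladder(), run = sampling_run(200),
                         n_runs = 1, seed = 1, progress = FALSE) {
  rep_ <- plan$rep
  schedule <- build_schedule(rep_)
  temps <- ladder$temperatures
  nR <- ladder$n_replicas
  frames <- list(); scores <- list(); meta <- list()
  acc_stats <- list()
  for (rn in seq_len(n_runs)) {
    run_seed <- sub_seed(seed, rn)
    replicas <- vector("list", nR)
    rng_states <- vector("list", nR)
    for (r in seq_len(nR)) {
      coords <- with_seed(sub_seed(run_seed, r), init_fn(rep_, sub_seed(run_seed, r)))
      terms <- plan$score(coords)
      replicas[[r]] <- list(coords = coords, terms = terms,
                            total = sum(plan$weights * terms))
      # per-replica RNG stream
      set.seed(sub_seed(run_seed, 1000L + r))
      rng_states[[r]] <- get(".Random.seed", envir = globalenv())
    }
    set.seed(sub_seed(run_seed, 999L))
    exch_state <- get(".Random.seed", envir = globalenv())
    acc <- prop <- 0
    for (sw in seq_len(run$n_sweeps)) {
      for (r in seq_len(nR)) {
        assign(".Random.seed", rng_states[[r]], envir = globalenv())
        st <- gibbs_sweep(replicas[[r]], plan, movers, temps[r], schedule)
        rng_states[[r]] <- get(".Random.seed", envir = globalenv())
        replicas[[r]][c("coords", "terms", "total")] <-
          st[c("coords", "terms", "total")]
        acc <- acc + st$accepted; prop <- prop + st$proposed
      }
      if (nR > 1) {
        assign(".Random.seed", exch_state, envir = globalenv())
        ex <- replica_exchange_step(replicas, temps, parity = sw %% 2L)
        exch_state <- get(".Random.seed", envir = globalenv())
        replicas <- ex$replicas
      }
      if (sw %% run$save_period == 0L) {
        for (r in seq_len(nR)) {
          frames[[length(frames) + 1L]] <- replicas[[r]]$coords
          scores[[length(scores) + 1L]] <-
            c(replicas[[r]]$terms, total = replicas[[r]]$total)
          meta[[length(meta) + 1L]] <- data.frame(
            run = rn, replica = r, sweep = sw, temperature = temps[r])
        }
      }
    }
    acc_stats[[rn]] <- acc / max(prop, 1)
    if (progress)
      message(sprintf("run %d/%d: acceptance %.2f", rn, n_runs, acc_stats[[rn]]))
  }
  ensemble(frames = frames,
           scores = as.data.frame(do.call(rbind, scores)),
           meta = do.call(rbind, meta), rep = rep_,
           acceptance = unlist(acc_stats))
}

# ---- layer-aware initialization --------------------------------------------

#' Randomize upper-layer rigid bodies in a bounding box with polarity check
#'
#' Rigid bodies of the named proteins are placed uniformly inside \code{box}
#' with a uniform random orientation. If the body's N-to-C polarity along z
#' (sign of z at the C-end bead minus z at the N-end bead) contradicts the
#' polarity table, the body is flipped 180 degrees about a random axis in the
#' membrane plane, reversing the polarity while keeping the in-plane
#' orientation random. Flexible beads of those proteins are placed uniformly
#' in the box.
#'
#' @param rep representation; @param coords current coordinate matrix.
#' @param proteins character vector of protein names to initialize.
#' @param box list(min = c(x,y,z), max = c(x,y,z)).
#' @param polarity named character vector, \code{"N"} or \code{"C"}: which
#'   terminus of each protein must be membrane-proximal (smaller z).
#' @return Updated coordinate matrix.
#' @export
initialize_pg_layer <- function(rep, coords, proteins, box, polarity) {
  b <- rep$beads
  span <- box$max - box$min
  for (pn in proteins) {
    for (cp in seq_len(rep$topology$proteins[[pn]]$copies)) {
      rows <- which(b$protein == pn & b$copy == cp)
      bodies <- unique(b$rigid_body[rows])
      bodies <- bodies[!is.na(bodies)]
      for (bid in bodies) {
        idx <- which(b$rigid_body %in% bid)
        local <- sweep(rep$coords[idx, , drop = FALSE], 2,
                       colMeans(rep$coords[idx, , drop = FALSE]))
        ext <- max(row_dist(local, c(0, 0, 0)))
        if (any(span < 2 * ext))
          stop("bounding box too small to contain rigid body of '", pn, "'")
        R <- rand_rotation()
        ctr <- box$min + runif(3) * span
        placed <- sweep(local %*% t(R), 2, ctr, "+")
        # polarity along z from the body's terminal beads (by residue order)
        o <- order(b$res_start[idx])
        pol_now <- sign(placed[o[length(o)], 3] - placed[o[1], 3]) # C minus N
        want <- polarity[[pn]]
        pol_want <- if (identical(want, "N")) 1 else -1
        if (!is.na(pol_now) && pol_now != 0 && pol_now != pol_want) {
          phi <- runif(1, 0, 2 * pi)
          Rf <- rotation_about_axis(c(cos(phi), sin(phi), 0), pi)
          placed <- sweep(sweep(placed, 2, ctr) %*% t(Rf), 2, ctr, "+")
          pol_post <- sign(placed[o[length(o)], 3] - placed[o[1], 3])
          stopifnot(pol_post == pol_want)
        }
        coords[idx, ] <- placed
      }
      flex <- rows[is.na(b$rigid_body[rows]) & b$mobile[rows]]
      if (length(flex))
        coords[flex, ] <- matrix(box$min, length(flex), 3, byrow = TRUE) +
          matrix(runif(3 * length(flex)), ncol = 3) *
          matrix(span, length(flex), 3, byrow = TRUE)
    }
  }
  coords
}

#' Initialize lower-layer molecules around molecule-wise densities
#'
#' Each mobile copy of the named proteins is centered (rigid bodies first) at
#' its assigned density centroid with a uniform random orientation; copies and
#' centroids are matched 1:1 in order. Flexible beads of the copy are dropped
#' near the body with jitter. Fixed (immobile) beads are left at their fitted
#' poses from the representation.
#'
#' @param rep,coords as above.
#' @param proteins proteins of the layer.
#' @param centroids matrix (one row per mobile copy, in copy order) of
#'   molecule-wise density centers.
#' @param jitter flexible-bead placement jitter (A).
#' @return Updated coordinate matrix.
#' @export
initialize_pkp_layer <- function(rep, coords, proteins, centroids, jitter = 10) {
  b <- rep$beads
  ci <- 0L
  for (pn in proteins) {
    for (cp in seq_len(rep$topology$proteins[[pn]]$copies)) {
      rows <- which(b$protein == pn & b$copy == cp)
      if (!any(b$mobile[rows])) next        # fixed copy: keep fitted pose
      ci <- ci + 1L
      if (ci > nrow(centroids))
        stop("fewer molecule densities than mobile copies")
      ctr <- centroids[ci, ]
      bodies <- unique(b$rigid_body[rows]); bodies <- bodies[!is.na(bodies)]
      for (bid in bodies) {
        idx <- which(b$rigid_body %in% bid)
        local <- sweep(rep$coords[idx, , drop = FALSE], 2,
                       colMeans(rep$coords[idx, , drop = FALSE]))
        coords[idx, ] <- sweep(local %*% t(rand_rotation()), 2, ctr, "+")
      }
      flex <- rows[is.na(b$rigid_body[rows]) & b$mobile[rows]]
      if (length(flex))
        coords[flex, ] <- matrix(ctr, length(flex), 3, byrow = TRUE) +
          matrix(runif(3 * length(flex), -jitter, jitter), ncol = 3)
    }
  }
  coords
}

#' Initialize an anchored flexible chain by a constrained random walk
#'
#' The anchored bead is placed on the membrane plane (z = 0) at a random
#' position inside the cylinder; subsequent beads of the copy walk upward with
#' steps bounded by the connectivity threshold.
#'
#' @param rep,coords as above.
#' @param proteins anchored chain proteins.
#' @param cyl_radius placement cylinder radius.
#' @param step_frac fraction of the connectivity threshold used as walk step.
#' @return Updated coordinate matrix.
#' @export
initialize_anchored_chain <- function(rep, coords, proteins, cyl_radius,
                                      step_frac = 0.9) {
  b <- rep$beads
  cp_tab <- consecutive_pairs(rep)
  for (pn in proteins) {
    for (cp in seq_len(rep$topology$proteins[[pn]]$copies)) {
      rows <- which(b$protein == pn & b$copy == cp)
      rows <- rows[order(b$res_start[rows])]
      rho <- sqrt(runif(1)) * cyl_radius * 0.8
      phi <- runif(1, 0, 2 * pi)
      coords[rows[1], ] <- c(rho * cos(phi), rho * sin(phi), 0)
      if (length(rows) > 1) for (i in 2:length(rows)) {
        pr <- cp_tab[cp_tab$i == rows[i - 1] & cp_tab$j == rows[i], ]
        step <- step_frac * pr$threshold[1]
        dir <- rnorm(3); dir[3] <- abs(dir[3]) + 0.5
        dir <- dir / sqrt(sum(dir^2))
        coords[rows[i], ] <- coords[rows[i - 1], ] + step * dir
      }
    }
  }
  coords
}
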