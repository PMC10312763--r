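#' Integrated autocorrelation time of a trace
#'
#' \eqn{\tau = 1 + 2\sum_k \rho_k}, truncated at the first non-positive
#' autocorrelation (initial positive sequence), floored at 1.
#'
#' @param x numeric trace.
#' @return Estimated autocorrelation time (>= 1).
#' @export
autocorrelation_time <- function(x) {
  n <- length(x)
  if (n < 3 || sd(x) == 0) return(1)
  r <- acf(x, lag.max = min(n - 2, 1000), plot = FALSE)$acf[-1]
  neg <- which(r <= 0)
  if (length(neg)) r <- r[seq_len(neg[1] - 1)]
  max(1, 1 + 2 * sum(r))
}

#' Geweke-style z statistic between two trace segments
#' @noRd
geweke_z <- function(x, first = 0.1, last = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2, floor(first * n)))]
  b <- x[seq(n - max(2, floor(last * n)) + 1, n)]
  na <- length(a) / autocorrelation_time(a)
  nb <- length(b) / autocorrelation_time(b)
  se <- sqrt(var(a) / na + var(b) / nb)
  if (se == 0) return(0)
  (mean(a) - mean(b)) / se
}

#' Detect burn-in of a score trace
#'
#' Smallest burn-in (on a grid of fractions of the trace) for which the
#' Geweke comparison of the first 10\% against the last 50\% of the remaining
#' trace gives |z| below the criterion.
#'
#' @param x numeric trace.
#' @param z_crit z threshold (default 2).
#' @param grid candidate burn-in fractions.
#' @return Number of frames to discard, or \code{NA} if no candidate passes.
#' @export
detect_burn_in <- function(x, z_crit = 2, grid = seq(0, 0.6, by = 0.025)) {
  n <- length(x)
  for (g in grid) {
    b <- floor(g * n)
    if (n - b < 20) break
    if (abs(geweke_z(x[(b + 1):n])) < z_crit) return(b)
  }
  NA_integer_
}

#' Equilibration and autocorrelation filter
#'
#' Per run and replica slot, discards frames before the total-score trace
#' equilibrates (Geweke-style burn-in detection) and thins the remainder by
#' the integrated autocorrelation time of the total score. Traces that never
#' equilibrate are excluded with a warning.
#'
#' @param ens an \code{\link{ensemble}}.
#' @param z_crit Geweke z criterion (default 2).
#' @return A filtered ensemble; attribute \code{"filter_info"} records
#'   burn-in and thinning per trace.
#' @export
equilibration_filter <- function(ens, z_crit = 2) {
  keep <- integer(0)
  info <- list()
  groups <- split(seq_len(n_frames(ens)),
                  paste(ens$meta$run, ens$meta$replica))
  for (g in names(groups)) {
    idx <- groups[[g]][order(ens$meta$sweep[groups[[g]]])]
    tr <- ens$scores$total[idx]
    b <- detect_burn_in(tr, z_crit)
    if (is.na(b)) {
      warning("trace ", g, " never equilibrates; excluded")
      next
    }
    post <- idx[(b + 1):length(idx)]
    thin <- max(1L, ceiling(autocorrelation_time(ens$scores$total[post])))
    keep <- c(keep, post[seq(1, length(post), by = thin)])
    info[[g]] <- c(burn_in = b, thin = thin)
  }
  if (!length(keep)) stop("no run equilibrated")
  out <- subset_ensemble(ens, sort(keep))
  attr(out, "filter_info") <- info
  out
}

#' Density-based clustering of frames in restraint-score space
#'
#' DBSCAN-style clustering on the scaled per-term score vectors; the largest
#' cluster is retained (noise label allowed). \code{eps} defaults to the 0.9
#' quantile of the min_pts-nearest-neighbor distance, a standard heuristic.
#'
#' @param ens an ensemble.
#' @param eps neighborhood radius in scaled score space (default: heuristic).
#' @param min_pts minimum neighborhood size for a core point.
#' @return The retained sub-ensemble; attribute \code{"labels"} holds the full
#'   label vector (0 = noise).
#' @export
score_space_cluster <- function(ens, eps = NULL, min_pts = 5) {
  feat <- as.matrix(ens$scores[, setdiff(names(ens$scores), "total")])
  feat <- feat[, apply(feat, 2, sd) > 0, drop = FALSE]
  if (!ncol(feat)) {      # all terms constant: one tight blob
    labels <- rep(1L, n_frames(ens))
  } else {
    feat <- scale(feat)
    d <- as.matrix(dist(feat))
    if (is.null(eps)) {
      knn <- apply(d, 1, function(r) sort(r)[min(min_pts + 1, length(r))])
      eps <- max(quantile(knn, 0.9), 1e-8)
    }
    labels <- dbscan_labels(d, eps, min_pts)
  }
  if (all(labels == 0)) stop("all frames labeled noise; increase eps/min_pts")
  sizes <- table(labels[labels > 0])
  top <- as.integer(names(sizes)[which.max(sizes)])
  out <- subset_ensemble(ens, which(labels == top))
  attr(out, "labels") <- labels
  out
}

#' DBSCAN core from a precomputed distance matrix
#' @noRd
dbscan_labels <- function(d, eps, min_pts) {
  n <- nrow(d)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      for (m in nb[[q]]) {
        if (labels[m] == 0L) {
          labels[m] <- cl
          if (core[m]) queue <- c(queue, m)
        }
      }
    }
  }
  labels
}

#' Good-scoring filter
#'
#' Keeps frames whose every per-term score and total score beat the
#' corresponding mean plus \code{n_sd} standard deviations (means and SDs over
#' the input set). Terms with zero SD are compared as <= mean, so perfectly
#' converged terms are never discarded.
#'
#' @param ens an ensemble.
#' @param n_sd the SD multiplier (default 1.46).
#' @return The retained sub-ensemble.
#' @export
good_scoring_filter <- function(ens, n_sd = 1.46) {
  sc <- ens$scores
  ok <- rep(TRUE, nrow(sc))
  for (cn in names(sc)) {
    m <- mean(sc[[cn]]); s <- sd(sc[[cn]])
    ok <- ok & if (s == 0) sc[[cn]] <= m else sc[[cn]] < m + n_sd * s
  }
  if (!any(ok)) stop("good-scoring filter retained no frames")
  subset_ensemble(ens, which(ok))
}

# ---- ambiguity-aware RMSD ---------------------------------------------------

#' Hungarian algorithm for the assignment problem
#'
#' O(n^3) shortest-augmenting-path solver (Jonker-Volgenant style) for a
#' square cost matrix; returns the column assigned to each row.
#'
#' @param cost square numeric cost matrix.
#' @return Integer vector \code{p} with row i assigned to column \code{p[i]}.
#' @export
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0 + 0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n) + 1L) if (p[j] > 0) ans[p[j]] <- j - 1L
  ans
}

#' Copy grouping of a representation for RMSD computations
#'
#' For each protein: a slots x copies matrix of bead row indices and the
#' interchangeability flag (proteins containing fixed beads are matched by
#' copy index, mirroring density-fitted immobile copies that pin identity).
#' @param rep an \code{assembly_representation}.
#' @return List used by \code{\link{ambiguous_rmsd}}.
#' @export
rmsd_grouping <- function(rep) {
  b <- rep$beads
  lapply(rep$topology$proteins, function(p) {
    rows1 <- which(b$protein == p$name & b$copy == 1)
    rows1 <- rows1[order(b$res_start[rows1])]
    idx <- vapply(seq_len(p$copies), function(cp) {
      r <- which(b$protein == p$name & b$copy == cp)
      r[order(b$res_start[r])]
    }, integer(length(rows1)))
    has_fixed <- any(!b$mobile[b$protein == p$name])
    list(idx = matrix(idx, nrow = length(rows1)),
         interchangeable = p$interchangeable && !has_fixed)
  })
}

#' Ambiguity-aware RMSD between two models
#'
#' Bead-wise RMSD in the common (fixed) frame, minimized over bipartite
#' pairings of equivalent protein copies: for each interchangeable protein the
#' copy-vs-copy summed-squared-distance cost matrix is built and the
#' assignment problem solved; non-interchangeable proteins are matched by
#' copy index. No superposition is performed.
#'
#' @param ca,cb N x 3 coordinate matrices over the same representation.
#' @param grouping output of \code{\link{rmsd_grouping}} (or a representation,
#'   from which it is computed).
#' @return RMSD in Angstrom.
#' @export
ambiguous_rmsd <- function(ca, cb, grouping) {
  if (inherits(grouping, "assembly_representation"))
    grouping <- rmsd_grouping(grouping)
  if (nrow(ca) != nrow(cb)) stop("models have different bead counts")
  ssd_tot <- 0; nb <- 0L
  for (g in grouping) {
    nc <- ncol(g$idx); ns <- nrow(g$idx)
    nb <- nb + nc * ns
    if (nc == 1 || !g$interchangeable) {
      for (cp in seq_len(nc)) {
        ia <- g$idx[, cp]
        ssd_tot <- ssd_tot + sum((ca[ia, ] - cb[ia, ])^2)
      }
    } else {
      cost <- matrix(0, nc, nc)
      for (i in seq_len(nc)) for (j in seq_len(nc))
        cost[i, j] <- sum((ca[g$idx[, i], ] - cb[g$idx[, j], ])^2)
      asg <- solve_assignment(cost)
      ssd_tot <- ssd_tot + sum(cost[cbind(seq_len(nc), asg)])
    }
  }
  sqrt(ssd_tot / nb)
}

#' Pairwise ambiguity-aware RMSD matrix of an ensemble
#' @param ens an ensemble (or list of coordinate matrices + grouping).
#' @param grouping optional precomputed grouping.
#' @return Symmetric n x n matrix.
#' @export
rmsd_matrix <- function(ens, grouping = NULL) {
  frames <- if (inherits(ens, "ensemble")) ens$frames else ens
  if (is.null(grouping)) grouping <- rmsd_grouping(ens$rep)
  n <- length(frames)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- ambiguous_rmsd(frames[[i]], frames[[j]], grouping)
  }
  m
}

# ---- exhaustiveness and structural clustering ------------------------------

#' Threshold-based greedy clustering from a distance matrix
#'
#' Repeatedly takes the unassigned frame with the most unassigned neighbors
#' within the threshold (ties broken by frame index) as a cluster center and
#' assigns it and those neighbors to a new cluster. Deterministic.
#' @noRd
greedy_cluster_labels <- function(d, threshold) {
  n <- nrow(d)
  labels <- integer(n)
  cl <- 0L
  repeat {
    un <- which(labels == 0L)
    if (!length(un)) break
    counts <- vapply(un, function(i) sum(d[i, un] <= threshold), integer(1))
    center <- un[which.max(counts)]
    cl <- cl + 1L
    members <- un[d[center, un] <= threshold]
    labels[members] <- cl
  }
  labels
}

#' Sampling-exhaustiveness test
#'
#' Divides the models into two independent sets (by run when several runs are
#' present, otherwise by a seeded random half-split), then tests (i) score
#' similarity via a two-sample Kolmogorov-Smirnov test on total scores and
#' (ii) structural similarity: at each clustering threshold, the pooled models
#' are cluster-labeled and the per-cluster populations of the two halves are
#' compared by a chi-square test and Cramer's V. The sampling precision is the
#' smallest threshold at which p > p_min, V < v_max and at least
#' \code{min_clustered} of the models fall in non-singleton clusters.
#'
#' @param ens an ensemble.
#' @param thresholds candidate thresholds (default: 20 quantiles of the
#'   pairwise RMSD distribution).
#' @param rmsd_mat optional precomputed \code{\link{rmsd_matrix}}.
#' @param split \code{"run"} or \code{"random"}.
#' @param seed seed for the random split.
#' @param p_min,v_max,min_clustered pass criteria (defaults 0.05, 0.10, 0.80).
#' @return List: \code{ks_p}, per-threshold data frame \code{tests},
#'   \code{sampling_precision} (NA if sampling is not exhaustive),
#'   \code{pass}.
#' @export
exhaustiveness_test <- function(ens, thresholds = NULL, rmsd_mat = NULL,
                                split = c("run", "random"), seed = 1,
                                p_min = 0.05, v_max = 0.10,
                                min_clustered = 0.80) {
  split <- match.arg(split)
  n <- n_frames(ens)
  runs <- unique(ens$meta$run)
  if (split == "run" && length(runs) >= 2) {
    h1 <- runs[seq_len(floor(length(runs) / 2))]
    half <- ifelse(ens$meta$run %in% h1, 1L, 2L)
  } else {
    half <- with_seed(seed, sample(rep(1:2, length.out = n)))
  }
  if (is.null(rmsd_mat)) rmsd_mat <- rmsd_matrix(ens)
  if (is.null(thresholds)) {
    dv <- rmsd_mat[upper.tri(rmsd_mat)]
    thresholds <- unique(quantile(dv, seq(0.05, 1, by = 0.05), names = FALSE))
  }
  ks <- suppressWarnings(
    ks.test(ens$scores$total[half == 1], ens$scores$total[half == 2]))
  rows <- lapply(sort(thresholds), function(th) {
    labels <- greedy_cluster_labels(rmsd_mat, th)
    sizes <- table(labels)
    keep_cl <- as.integer(names(sizes)[sizes >= 2])
    frac_cl <- sum(labels %in% keep_cl) / n
    inc <- labels %in% keep_cl
    if (length(keep_cl) < 2) {
      p <- 1; v <- 0
    } else {
      tab <- table(factor(labels[inc]), factor(half[inc], levels = 1:2))
      chs <- suppressWarnings(chisq.test(tab))
      p <- chs$p.value
      v <- sqrt(chs$statistic / sum(tab))
      if (!is.finite(p)) { p <- 1; v <- 0 }
    }
    data.frame(threshold = th, p_value = p, cramers_v = as.numeric(v),
               frac_clustered = frac_cl, n_clusters = length(sizes))
  })
  tests <- do.call(rbind, rows)
  ok <- tests$p_value > p_min & tests$cramers_v < v_max &
    tests$frac_clustered >= min_clustered
  sp <- if (any(ok)) tests$threshold[which(ok)[1]] else NA_real_
  list(ks_p = ks$p.value, tests = tests, sampling_precision = sp,
       pass = !is.na(sp), half = half)
}

#' Structural clustering at a threshold
#'
#' Greedy centroid clustering of the ensemble with the ambiguity-aware RMSD
#' at the given threshold (normally the sampling precision). The centroid of a
#' cluster is its member minimizing the summed RMSD to all members; the model
#' precision is the mean member-to-centroid RMSD of the largest cluster.
#'
#' @param ens an ensemble.
#' @param threshold clustering threshold in Angstrom.
#' @param rmsd_mat optional precomputed matrix.
#' @return A \code{cluster_result}: labels, per-cluster centroid frame ids,
#'   cluster sizes, \code{sampling_precision} (= threshold),
#'   \code{model_precision}.
#' @export
structural_cluster <- function(ens, threshold, rmsd_mat = NULL) {
  if (is.null(rmsd_mat)) rmsd_mat <- rmsd_matrix(ens)
  labels <- greedy_cluster_labels(rmsd_mat, threshold)
  sizes <- table(labels)
  centroids <- vapply(as.integer(names(sizes)), function(cl) {
    mem <- which(labels == cl)
    mem[which.min(rowSums(rmsd_mat[mem, mem, drop = FALSE]))]
  }, integer(1))
  major <- as.integer(names(sizes)[which.max(sizes)])
  mem <- which(labels == major)
  ctr <- centroids[match(major, as.integer(names(sizes)))]
  mp <- if (length(mem) > 1) mean(rmsd_mat[ctr, setdiff(mem, ctr)]) else 0
  structure(list(labels = labels, centroids = centroids,
                 sizes = as.integer(sizes), major = major,
                 major_centroid = ctr,
                 sampling_precision = threshold, model_precision = mp),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$sizes), " cluster(s); major: ",
      max(x$sizes), " models, model precision ",
      signif(x$model_precision, 4), " A\n", sep = "")
  invisible(x)
}

#' Localization probability density of a domain
#'
#' Voxel value = fraction of the given models in which at least one bead of
#' the domain's sphere intersects the voxel (sphere-box test via coordinate
#' clamping).
#'
#' @param ens ensemble (typically the major cluster members).
#' @param protein,domain domain selector; \code{domain = NULL} selects the
#'   whole protein.
#' @param voxel voxel edge (A), default 5.
#' @param bounds optional list(min, max); default: ensemble bounding box
#'   padded by the largest bead radius.
#' @return A \code{\link{density_map}} with values in [0, 1].
#' @export
localization_density <- function(ens, protein, domain = NULL, voxel = 5,
                                 bounds = NULL) {
  if (!n_frames(ens)) stop("empty model set")
  b <- ens$rep$beads
  sel <- b$protein == protein
  if (!is.null(domain)) sel <- sel & b$domain == domain
  if (!any(sel)) stop("no beads match the domain selector")
  sel <- which(sel)
  rmax <- max(b$radius[sel])
  if (is.null(bounds)) {
    all_xyz <- do.call(rbind, lapply(ens$frames, function(f) f[sel, , drop = FALSE]))
    bounds <- list(min = apply(all_xyz, 2, min) - rmax - voxel,
                   max = apply(all_xyz, 2, max) + rmax + voxel)
  }
  dims <- pmax(1L, as.integer(ceiling((bounds$max - bounds$min) / voxel)) + 1L)
  counts <- array(0, dims)
  org <- bounds$min
  for (f in ens$frames) {
    hit <- array(FALSE, dims)
    for (i in sel) {
      ctr <- f[i, ]; r <- b$radius[i]
      lo <- pmax(1L, as.integer(floor((ctr - r - org) / voxel)) + 1L)
      hi <- pmin(dims, as.integer(ceiling((ctr + r - org) / voxel)) + 1L)
      if (any(lo > hi)) next
      ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
      vx <- org[1] + (ii - 1) * voxel
      vy <- org[2] + (jj - 1) * voxel
      vz <- org[3] + (kk - 1) * voxel
      # clamp bead center to each voxel cube; inside if clamped point within r
      h <- voxel / 2
      cx <- pmin(pmax(ctr[1], vx - h), vx + h)
      cy <- pmin(pmax(ctr[2], vy - h), vy + h)
      cz <- pmin(pmax(ctr[3], vz - h), vz + h)
      d2 <- outer(outer((cx - ctr[1])^2, (cy - ctr[2])^2, "+"),
                  (cz - ctr[3])^2, "+")
      hit[ii, jj, kk] <- hit[ii, jj, kk] | (d2 <= r^2)
    }
    counts <- counts + hit
  }
  density_map(counts / length(ens$frames), voxel, org)
}
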