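#' Ensemble of sampled models
#'
#' Container for sampled configurations: a list of N x 3 coordinate matrices,
#' a per-frame score table (six restraint terms + total), per-frame provenance
#' (run, replica, sweep, temperature), and the shared representation.
#'
#' @param frames list of coordinate matrices.
#' @param scores data frame, one row per frame.
#' @param meta data frame, one row per frame.
#' @param rep the \code{assembly_representation}.
#' @param acceptance optional per-run acceptance rates.
#' @export
ensemble <- function(frames, scores, meta, rep, acceptance = NULL) {
  stopifnot(length(frames) == nrow(scores), length(frames) == nrow(meta))
  structure(list(frames = frames, scores = scores, meta = meta, rep = rep,
                 acceptance = acceptance),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble> ", length(x$frames), " frames, ",
      length(unique(x$meta$run)), " run(s)\n", sep = "")
  invisible(x)
}

#' Number of frames
#' @param ens an ensemble.
#' @export
n_frames <- function(ens) length(ens$frames)

#' Subset an ensemble by frame index
#' @param ens an ensemble; @param idx frame indices to keep.
#' @export
subset_ensemble <- function(ens, idx) {
  ensemble(ens$frames[idx], ens$scores[idx, , drop = FALSE],
           ens$meta[idx, , drop = FALSE], ens$rep, ens$acceptance)
}

#' Write / read an ensemble trajectory as CSV
#'
#' Long-format per-frame table: one row per bead per frame with frame index,
#' provenance, bead id and coordinates; the per-frame score table is written
#' alongside with suffix \code{_scores.csv}. Reading requires the matching
#' representation.
#'
#' @param ens an \code{\link{ensemble}}.
#' @param path base CSV path.
#' @export
write_trajectory <- function(ens, path) {
  nb <- nrow(ens$rep$beads)
  tab <- do.call(rbind, lapply(seq_along(ens$frames), function(f) {
    data.frame(frame = f, run = ens$meta$run[f], replica = ens$meta$replica[f],
               sweep = ens$meta$sweep[f], bead = seq_len(nb),
               x = ens$frames[[f]][, 1], y = ens$frames[[f]][, 2],
               z = ens$frames[[f]][, 3])
  }))
  write.csv(tab, path, row.names = FALSE)
  sc <- cbind(frame = seq_len(n_frames(ens)), ens$meta, ens$scores)
  write.csv(sc, sub("\\.csv$", "_scores.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param rep the representation the trajectory was sampled with.
#' @export
read_trajectory <- function(path, rep) {
  tab <- read.csv(path)
  sc <- read.csv(sub("\\.csv$", "_scores.csv", path))
  fr <- split(tab, tab$frame)
  frames <- lapply(fr, function(d) {
    m <- as.matrix(d[order(d$bead), c("x", "y", "z")])
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
  })
  meta <- sc[, c("run", "replica", "sweep",
                 intersect("temperature", names(sc)))]
  scores <- sc[, setdiff(names(sc), c("frame", "run", "replica", "sweep",
                                      "temperature"))]
  ensemble(unname(frames), scores, meta, rep)
}

#' Export ensemble frames as a multi-model bead PDB
#'
#' One MODEL per frame, one CA pseudo-atom per bead (occupancy 1, B-factor =
#' bead radius) for visualization in standard molecular graphics tools.
#'
#' @param ens an ensemble.
#' @param path output PDB path.
#' @param frames frame indices (default: all).
#' @export
ensemble_to_pdb <- function(ens, path, frames = seq_len(n_frames(ens))) {
  b <- ens$rep$beads
  chains <- LETTERS[as.integer(factor(paste(b$protein, b$copy)))]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ens$frames[[f]]
    lines <- sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          C",
      seq_len(nrow(b)) %% 100000, chains, b$slot + (b$res_start %/% 1000),
      xyz[, 1], xyz[, 2], xyz[, 3], 1, b$radius)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  invisible(path)
}
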