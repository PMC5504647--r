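# Pose evaluation and decoy post-processing: ligand RMSD, near-duplicate
# filtering, the three-stage ranking scheme, temperature-occupancy and
# funnel diagnostics.

.coords_heavy <- function(x) {
  if (inherits(x, "dock_pose")) {
    m <- ligand_coords(x)
    return(m[!x$lig_is_h, , drop = FALSE])
  }
  if (is.data.frame(x)) {
    h <- if (!is.null(x$is_hydrogen)) x$is_hydrogen else rep(FALSE, nrow(x))
    return(.atom_xyz(x)[!h, , drop = FALSE])
  }
  as.matrix(x)
}

#' Ligand RMSD (Lrmsd)
#'
#' Root-mean-square deviation over non-hydrogen ligand atoms, computed in
#' the fixed receptor frame without superposition (standard docking
#' Lrmsd).  Atom count and order must match.  `Lrmsd <= 2` Angstrom is
#' the conventional docking success criterion.
#'
#' @param pred_ligand,native_ligand ligand coordinates: `n x 3` matrices,
#'   atom tables, or poses (hydrogens dropped for tables/poses).
#' @return the RMSD in Angstrom.
#' @export
lrmsd <- function(pred_ligand, native_ligand) {
  a <- .coords_heavy(pred_ligand)
  b <- .coords_heavy(native_ligand)
  if (nrow(a) != nrow(b))
    stop("ligand atom counts differ (", nrow(a), " vs ", nrow(b), ")")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Near-duplicate threshold
#'
#' `0.65 * sqrt(N)` Angstrom, `N` the number of non-hydrogen ligand atoms.
#'
#' @param n_heavy non-hydrogen ligand atom count.
#' @return threshold in Angstrom.
#' @export
near_duplicate_threshold <- function(n_heavy) 0.65 * sqrt(n_heavy)

#' Stochastic elimination of near-duplicate decoys
#'
#' Visits the decoys in a random order (current RNG; seed for
#' reproducibility) and drops any decoy whose ligand RMSD to an
#' already-kept decoy is below the threshold.  All kept decoys are
#' therefore pairwise at least `threshold` apart.
#'
#' @param coords list of ligand coordinate matrices (non-hydrogen atoms,
#'   shared atom order).
#' @param threshold RMSD threshold in Angstrom; defaults to
#'   [near_duplicate_threshold()] of the atom count.
#' @return integer indices of the kept decoys, in increasing order.
#' @export
filter_near_duplicates <- function(coords, threshold = NULL) {
  m <- length(coords)
  if (m == 0L) return(integer(0))
  if (is.null(threshold))
    threshold <- near_duplicate_threshold(nrow(coords[[1]]))
  order_visit <- sample.int(m)
  kept <- integer(0)
  for (i in order_visit) {
    dup <- FALSE
    for (j in kept) {
      if (lrmsd(coords[[i]], coords[[j]]) < threshold) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, i)
  }
  sort(kept)
}

#' Is the ligand touching the receptor?
#'
#' `TRUE` iff any ligand atom lies within `contact_radius` (default the
#' coarse-grained outer contact radius, 4.75 Angstrom) of any receptor
#' atom.
#'
#' @param pose a [new_pose()].
#' @param contact_radius contact cutoff in Angstrom.
#' @return logical.
#' @export
ligand_is_touching <- function(pose, contact_radius = 4.75) {
  d <- .cross_dist(pose$rec_xyz, ligand_coords(pose))
  any(d < contact_radius)
}

#' Three-stage decoy ranking
#'
#' Stage 1 discards decoys whose ligand is not touching the receptor;
#' stage 2 keeps the `max(1, floor(0.05 m))` lowest-total-energy
#' survivors (the top 5%, never empty for a non-empty touching pool);
#' stage 3 ranks those by ascending interface delta.
#'
#' @param decoys data frame with columns `tscore`, `ifdelta` and
#'   `touching` (e.g. from [decoys_from_archive()]).
#' @param top_fraction stage-2 fraction (default 0.05).
#' @return the ranked subset of `decoys` with a `rank` column; empty
#'   (with a warning) when no decoy touches the receptor.
#' @export
rank_decoys <- function(decoys, top_fraction = 0.05) {
  stopifnot(all(c("tscore", "ifdelta", "touching") %in% names(decoys)))
  pool <- decoys[decoys$touching, , drop = FALSE]
  if (nrow(pool) == 0L) {
    warning("no decoy has the ligand touching the receptor; empty ranking")
    out <- pool
    out$rank <- integer(0)
    return(out)
  }
  n_keep <- max(1L, floor(top_fraction * nrow(pool)))
  pool <- pool[order(pool$tscore)[seq_len(n_keep)], , drop = FALSE]
  pool <- pool[order(pool$ifdelta), , drop = FALSE]
  pool$rank <- seq_len(nrow(pool))
  rownames(pool) <- NULL
  pool
}

#' Temperature-occupancy diagnostic
#'
#' Per-replica visit frequency at each temperature rung over the run,
#' with per-replica mean and variance of the rung index (the red-point
#' statistics of the flattening diagnostic).  Each replica's row sums
#' to 1.
#'
#' @param rungs cycles x replicas matrix of rung indices (the `occupancy`
#'   field of an [remc_run()] result).
#' @param n_rungs total number of rungs (default: the maximum observed).
#' @return list of class `occupancy_matrix`: `occupancy` (replicas x
#'   rungs), `mean_rung`, `var_rung`.
#' @export
temperature_occupancy <- function(rungs, n_rungs = max(rungs)) {
  stopifnot(nrow(rungs) >= 1)
  numR <- ncol(rungs)
  occ <- t(apply(rungs, 2, function(col)
    tabulate(col, nbins = n_rungs) / length(col)))
  occ <- matrix(occ, nrow = numR, ncol = n_rungs)
  structure(list(
    occupancy = occ,
    mean_rung = colMeans(rungs),
    var_rung = apply(rungs, 2, function(col) {
      if (length(col) > 1) var(col) else 0
    })), class = "occupancy_matrix")
}

#' Funnel table
#'
#' One row per decoy with `(lrmsd, ifdelta, tscore)` for the
#' binding-energy-versus-RMSD funnel plot, plus the `Lrmsd <= 2` Angstrom
#' success flag.
#'
#' @param decoys data frame with columns `lrmsd`, `ifdelta`, `tscore`.
#' @param success_cutoff success criterion in Angstrom (default 2).
#' @return data frame with columns `lrmsd`, `ifdelta`, `tscore`,
#'   `success`.
#' @export
funnel_table <- function(decoys, success_cutoff = 2) {
  stopifnot(all(c("lrmsd", "ifdelta", "tscore") %in% names(decoys)))
  data.frame(lrmsd = decoys$lrmsd, ifdelta = decoys$ifdelta,
             tscore = decoys$tscore,
             success = decoys$lrmsd <= success_cutoff)
}

#' Decoy records from a sampling archive
#'
#' Evaluates interface delta, the touching flag and (when a native pose
#' is known) the Lrmsd for archived poses.
#'
#' @param archive an [new_archive()] whose states are poses (or an
#'   `mc_result`/`remc_result`, whose archive is used).
#' @param model an [energy_model()] for the interface delta.
#' @param native optional native pose (or ligand coordinates) for Lrmsd.
#' @param indices optional subset of archive entries (default: all).
#' @return data frame with columns `index`, `step`, `tscore`, `ifdelta`,
#'   `touching` and (if `native` given) `lrmsd`; ligand coordinate
#'   matrices attached as attribute `"coords"`.
#' @export
decoys_from_archive <- function(archive, model, native = NULL,
                                indices = NULL) {
  if (inherits(archive, c("mc_result", "remc_result")))
    archive <- archive$archive
  if (is.null(indices)) indices <- seq_len(archive_length(archive))
  states <- archive_states(archive, indices)
  nat <- if (!is.null(native)) .coords_heavy(native)
  out <- data.frame(index = indices,
                    step = archive$step[indices],
                    tscore = archive$tscore[indices],
                    ifdelta = NA_real_, touching = NA)
  coords <- vector("list", length(indices))
  for (i in seq_along(states)) {
    p <- states[[i]]
    out$ifdelta[i] <- interface_delta(p, model)
    out$touching[i] <- ligand_is_touching(p)
    coords[[i]] <- .coords_heavy(p)
    if (!is.null(nat)) out$lrmsd[i] <- sqrt(mean(rowSums((coords[[i]] - nat)^2)))
  }
  attr(out, "coords") <- coords
  out
}
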