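# Movers: proposal operators that perturb a pose.  All movers are
# functional (the input pose is never mutated) and preserve ligand atom
# identity/order, so ligand RMSDs between poses stay comparable.

#' Mover magnitudes
#'
#' The trial mover makes small rigid-body perturbations; the repack
#' surrogate makes larger ones and always resamples the conformer,
#' standing in for periodic side-chain repacking (the receptor itself is
#' held rigid).  Magnitudes are not prescribed by the sampling algorithms;
#' these defaults are package choices.
#'
#' @param trial_translation_sd Gaussian translation s.d. of the trial
#'   mover, Angstrom.
#' @param trial_rotation_sd Gaussian rotation-angle s.d. of the trial
#'   mover, degrees.
#' @param repack_translation_sd,repack_rotation_sd as above for the repack
#'   surrogate.
#' @param conformer_swap_prob probability that a trial move also swaps to
#'   a uniformly chosen conformer.
#' @return a list of class `move_config`.
#' @export
move_config <- function(trial_translation_sd = 0.2, trial_rotation_sd = 5,
                        repack_translation_sd = 1.0, repack_rotation_sd = 30,
                        conformer_swap_prob = 0.2) {
  stopifnot(trial_translation_sd >= 0, trial_rotation_sd >= 0,
            repack_translation_sd >= 0, repack_rotation_sd >= 0,
            conformer_swap_prob >= 0, conformer_swap_prob <= 1)
  structure(list(trial_translation_sd = trial_translation_sd,
                 trial_rotation_sd = trial_rotation_sd,
                 repack_translation_sd = repack_translation_sd,
                 repack_rotation_sd = repack_rotation_sd,
                 conformer_swap_prob = conformer_swap_prob),
            class = "move_config")
}

#' Small random rotation matrix
#'
#' Axis uniform on the sphere, angle Gaussian with s.d. `sd_deg` degrees
#' (an unbiased small-rotation proposal).  Draws from the current RNG.
#'
#' @param sd_deg angle standard deviation in degrees.
#' @return a 3x3 rotation matrix.
#' @export
random_rotation <- function(sd_deg) {
  ax <- rnorm(3)
  ang <- rnorm(1, 0, sd_deg * pi / 180)
  nrm <- sqrt(sum(ax^2))
  if (nrm < 1e-12) return(diag(3))
  ax <- ax / nrm
  # Rodrigues' formula
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

# exactly uniform random rotation (random unit quaternion)
.uniform_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

.rigid_perturb <- function(pose, trans_sd, rot_sd) {
  pose$center <- pose$center + rnorm(3, 0, trans_sd)
  pose$rotation <- random_rotation(rot_sd) %*% pose$rotation
  pose
}

#' Rotamer-trial mover
#'
#' Small Gaussian rigid-body perturbation of the ligand and, with
#' probability `conformer_swap_prob`, a uniformly chosen conformer swap.
#' Uses the current RNG; seed (or wrap in [with_stream()]) for
#' reproducibility.
#'
#' @param pose a [new_pose()].
#' @param cfg a [move_config()].
#' @return a new perturbed pose; the input is unmodified.
#' @export
rotamer_trial_move <- function(pose, cfg = move_config()) {
  pose <- .rigid_perturb(pose, cfg$trial_translation_sd, cfg$trial_rotation_sd)
  u <- runif(1)
  if (u < cfg$conformer_swap_prob)
    pose$conformer <- sample.int(length(pose$conformers), 1L)
  pose
}

#' Repack-surrogate mover
#'
#' Larger-amplitude rigid-body perturbation with a forced conformer
#' resample; the sampler-level stand-in for periodic side-chain repacking.
#'
#' @inheritParams rotamer_trial_move
#' @return a new perturbed pose.
#' @export
repack_surrogate_move <- function(pose, cfg = move_config()) {
  pose <- .rigid_perturb(pose, cfg$repack_translation_sd, cfg$repack_rotation_sd)
  pose$conformer <- sample.int(length(pose$conformers), 1L)
  pose
}

#' Dispatching proposal
#'
#' Applies [repack_surrogate_move()] when `step_index` is a positive
#' multiple of `repackNth`, otherwise [rotamer_trial_move()].
#'
#' @param pose a [new_pose()].
#' @param step_index the replica's step counter (1-based).
#' @param repackNth repack period; must be >= 1 (`repackNth = 1` makes
#'   every step a repack).
#' @param cfg a [move_config()].
#' @return the proposed pose.
#' @export
propose <- function(pose, step_index, repackNth, cfg = move_config()) {
  if (repackNth < 1) stop("repackNth must be >= 1")
  if (step_index > 0 && step_index %% repackNth == 0)
    repack_surrogate_move(pose, cfg)
  else
    rotamer_trial_move(pose, cfg)
}

#' Pose proposal function for the samplers
#'
#' Binds a [move_config()] and repack period into the
#' `function(state, local_step)` proposal interface used by
#' [mc_boltzmann()] and [remc_run()].
#'
#' @param cfg a [move_config()].
#' @param repackNth repack period (see [propose()]).
#' @return a proposal function.
#' @export
make_pose_proposer <- function(cfg = move_config(), repackNth = 5L) {
  force(cfg); force(repackNth)
  function(state, local_step) propose(state, local_step, repackNth, cfg)
}
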