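# Energy models: the coarse-grained contact score, the weighted full-atom
# score engine with surrogate terms, and the interface-delta binding energy.

#' Build an atom record table
#'
#' Atoms are plain data frames with one row per atom.  `role` classifies
#' each atom as receptor backbone, receptor side chain, or ligand; the
#' coarse-grained score's clash test runs against backbone atoms plus any
#' atom named `"CB"`.
#'
#' @param x,y,z Cartesian coordinates in Angstrom (finite).
#' @param element chemical element symbol(s).
#' @param name atom name(s), e.g. `"CA"`, `"CB"`.
#' @param role one of `"ligand"`, `"receptor-backbone"`,
#'   `"receptor-sidechain"` (recycled).
#' @param is_hydrogen logical flag; defaults to `element == "H"`.
#' @param eps per-atom attractive well-depth multiplier used by the
#'   surrogate terms (receptor atoms; a planted pocket deepens it).
#' @return a `data.frame` with columns `name`, `element`, `x`, `y`, `z`,
#'   `role`, `is_hydrogen`, `eps`.
#' @export
atom_records <- function(x, y, z, element = "C", name = element,
                         role = "ligand", is_hydrogen = NULL, eps = 1) {
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  if (!all(is.finite(x), is.finite(y), is.finite(z)))
    stop("atom coordinates must be finite")
  role <- rep_len(role, n)
  ok <- role %in% c("ligand", "receptor-backbone", "receptor-sidechain")
  if (!all(ok)) stop("unknown atom role: ", paste(unique(role[!ok]), collapse = ", "))
  element <- rep_len(element, n)
  if (is.null(is_hydrogen)) is_hydrogen <- element == "H"
  data.frame(name = rep_len(name, n), element = element,
             x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
             role = role, is_hydrogen = rep_len(is_hydrogen, n),
             eps = rep_len(as.numeric(eps), n),
             stringsAsFactors = FALSE)
}

# receptor x ligand distance matrix (rows = receptor atoms)
.cross_dist <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  sqrt(dx * dx + dy * dy + dz * dz)
}

.atom_xyz <- function(df) cbind(df$x, df$y, df$z)

#' Coarse-grained contact counts
#'
#' Counts, over non-hydrogen ligand atoms: `R`, atoms clashing with the
#' receptor backbone or C-beta atoms (distance strictly below
#' `clash_radius`); `A`, atoms in attractive contact with any receptor atom
#' (distance in the open interval (`clash_radius`, `contact_radius`)); and
#' `N`, the total count.  A clashing atom is never also counted as a
#' contact (clash takes precedence).
#'
#' @param receptor receptor atom table ([atom_records()]) or a
#'   [new_pose()] (in which case `ligand` is taken from the pose).
#' @param ligand ligand atom table.
#' @param clash_radius,contact_radius band boundaries in Angstrom
#'   (defaults 2.25 and 4.75).
#' @return an object of class `cg_counts`: list with `R`, `A`, `N`.
#' @seealso [coarse_grained_score()]
#' @export
coarse_grained_counts <- function(receptor, ligand = NULL,
                                  clash_radius = 2.25, contact_radius = 4.75) {
  if (inherits(receptor, "dock_pose")) {
    pose <- receptor
    receptor <- pose$receptor
    ligand <- ligand_atoms(pose)
  }
  heavy <- !ligand$is_hydrogen
  n <- sum(heavy)
  if (n < 1L) stop("ligand has no non-hydrogen atoms (N would be 0)")
  lxyz <- .atom_xyz(ligand)[heavy, , drop = FALSE]
  rxyz <- .atom_xyz(receptor)
  bbcb <- receptor$role == "receptor-backbone" | receptor$name == "CB"
  d <- .cross_dist(rxyz, lxyz)
  clash <- if (any(bbcb)) {
    apply(d[bbcb, , drop = FALSE], 2, min) < clash_radius
  } else rep(FALSE, n)
  in_band <- d > clash_radius & d < contact_radius
  contact <- apply(in_band, 2, any) & !clash
  structure(list(R = sum(clash), A = sum(contact), N = n),
            class = "cg_counts")
}

#' Coarse-grained complementarity score
#'
#' `S_cg = R - min(A/N, 0.85)`; lower is better.  `R` penalises clashes,
#' the saturating contact fraction rewards burial up to 85% of the ligand.
#'
#' @param counts a `cg_counts` object, or the clash count `R` if `A` and
#'   `N` are given separately.
#' @param A,N contact count and total ligand atom count (ignored when
#'   `counts` is a `cg_counts`).
#' @return the scalar score, bounded below by -0.85.
#' @export
coarse_grained_score <- function(counts, A = NULL, N = NULL) {
  if (inherits(counts, "cg_counts")) {
    R <- counts$R; A <- counts$A; N <- counts$N
  } else {
    R <- counts
  }
  stopifnot(N >= 1, R >= 0, A >= 0, R <= N, A <= N)
  R - min(A / N, 0.85)
}

# ---- full-atom score engine -------------------------------------------------

.TABLE1 <- data.frame(
  term = c("pro_close", "fa_atr", "fa_rep", "fa_sol", "fa_pair", "ref",
           "hbond_lr_bb", "hbond_sr_bb", "hbond_bb_sc", "hbond_sc",
           "rama", "omega"),
  hard = c(1.00, 0.80, 0.40, 0.60, 0.80, 1.00, 2.00, 2.00, 2.00, 2.00, 0.50, 0.50),
  soft = c(1.00, 0.80, 0.60, 0.50, 0.50, 1.00, 1.20, 1.20, 1.20, 1.20, 0.32, 0.50),
  stringsAsFactors = FALSE)

#' Score term names used by the full-atom engine
#' @return character vector of the twelve score-item names.
#' @export
score_term_names <- function() .TABLE1$term

#' Score weight presets
#'
#' Named weight vector for the weighted full-atom score.  The `"hard"`
#' preset is used during side-chain repacking, `"soft"` during rigid-body
#' minimisation.
#'
#' @param preset `"hard"` or `"soft"`.
#' @return a named numeric vector of class `score_weights` with a
#'   `preset` attribute.
#' @export
score_weights <- function(preset = c("hard", "soft")) {
  preset <- match.arg(preset)
  w <- setNames(.TABLE1[[preset]], .TABLE1$term)
  structure(w, class = "score_weights", preset = preset)
}

#' Read score weights from a key-value config file
#'
#' The file is YAML mapping term name to non-negative weight; unknown term
#' names are an error so typos do not silently score as zero.
#'
#' @param path file path.
#' @return a `score_weights` vector.
#' @export
read_score_weights <- function(path) {
  vals <- yaml::read_yaml(path)
  w <- unlist(vals)
  bad <- setdiff(names(w), .TABLE1$term)
  if (length(bad)) stop("unknown score terms in ", path, ": ",
                        paste(bad, collapse = ", "))
  if (any(w < 0)) stop("score weights must be non-negative")
  out <- setNames(numeric(length(.TABLE1$term)), .TABLE1$term)
  out[names(w)] <- w
  structure(out, class = "score_weights", preset = "custom")
}

#' Write score weights to a key-value config file
#' @param weights a `score_weights` vector.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_score_weights <- function(weights, path) {
  yaml::write_yaml(as.list(unclass(weights)), path)
  invisible(path)
}

#' Weighted full-atom score
#'
#' The linear combination `sum_i w_i s_i` over the score items in
#' `breakdown`.  Terms without a weight contribute zero (with a warning).
#'
#' @param breakdown named numeric vector of term values (`s_i`), e.g. from
#'   [surrogate_terms()].
#' @param weights a [score_weights()] vector (`w_i`).
#' @return the scalar weighted sum.
#' @export
full_atom_score <- function(breakdown, weights = score_weights("hard")) {
  s <- unclass(breakdown)
  if (is.null(names(s)) || any(!nzchar(names(s))))
    stop("breakdown must be a fully named numeric vector")
  if (any(is.na(s))) stop("NaN/NA score term value: ",
                          paste(names(s)[is.na(s)], collapse = ", "))
  w <- unclass(weights)[names(s)]
  miss <- is.na(w)
  if (any(miss)) {
    warning("no weight for term(s) ", paste(names(s)[miss], collapse = ", "),
            "; treated as weight 0")
    w[miss] <- 0
  }
  sum(w * s)
}

#' Parameters of the surrogate score terms
#'
#' Functional forms (documented simplifications; they reproduce the
#' weighted-sum combination semantics, not any production force field's
#' magnitudes):
#' * `fa_atr`: split 12-6 Lennard-Jones, attractive part.  Equal to
#'   `-depth * eps` for `d < lj_rmin`, the 12-6 well
#'   `depth * eps * ((rmin/d)^12 - 2 (rmin/d)^6)` out to `lj_cutoff`, 0
#'   beyond.  `eps` is the receptor atom's well-depth multiplier.
#' * `fa_rep`: the 12-6 potential shifted up by `depth` for `d < lj_rmin`
#'   (0 at `rmin`, continuous), capped at `rep_cap` so overlapping atoms
#'   stay finite for Metropolis arithmetic.
#' * `fa_sol`: burial penalty `sol_scale * exp(-d^2 / (2 sol_sd^2))`
#'   summed over pairs within the cutoff.
#' * `hbond_bb_sc` / `hbond_sc`: Gaussian well
#'   `-hbond_depth * eps * exp(-(d - hbond_d0)^2 / (2 hbond_sd^2))` over
#'   polar (N/O) receptor-backbone x polar-ligand, resp.
#'   receptor-sidechain x polar-ligand pairs; like `fa_atr` it scales
#'   with the receptor atom's `eps`, so a planted pocket deepens every
#'   attractive channel coherently.
#' * `pro_close`, `fa_pair`, `ref`, `hbond_lr_bb`, `hbond_sr_bb`, `rama`,
#'   `omega`: receptor-internal / sequence-statistics items; constant 0
#'   stubs under the rigid-receptor model.
#'
#' @param lj_rmin pair-potential minimum distance, Angstrom.
#' @param lj_depth base well depth, energy units.
#' @param lj_cutoff interaction cutoff, Angstrom.
#' @param rep_cap finite cap for the repulsive term at overlap.
#' @param hbond_d0,hbond_sd,hbond_depth Gaussian hydrogen-bond well
#'   centre, width, depth.
#' @param sol_sd,sol_scale burial-penalty Gaussian width and scale.
#' @return a list of class `surrogate_params`.
#' @export
surrogate_params <- function(lj_rmin = 3.6, lj_depth = 0.2, lj_cutoff = 12,
                             rep_cap = 1e4, hbond_d0 = 2.8, hbond_sd = 0.3,
                             hbond_depth = 1.0, sol_sd = 3.0, sol_scale = 0.05) {
  structure(list(lj_rmin = lj_rmin, lj_depth = lj_depth, lj_cutoff = lj_cutoff,
                 rep_cap = rep_cap, hbond_d0 = hbond_d0, hbond_sd = hbond_sd,
                 hbond_depth = hbond_depth, sol_sd = sol_sd,
                 sol_scale = sol_scale), class = "surrogate_params")
}

#' Surrogate score-term values for a pose
#'
#' Evaluates every score item named by [score_term_names()] on
#' receptor-ligand atom pairs; see [surrogate_params()] for the forms.
#' Deterministic in the pose; all values finite (overlap is capped).
#'
#' @param pose a [new_pose()].
#' @param params a [surrogate_params()] list.
#' @return named numeric vector of class `score_breakdown`.
#' @export
surrogate_terms <- function(pose, params = surrogate_params()) {
  stopifnot(inherits(pose, "dock_pose"))
  core <- .surrogate_core(pose, params)
  structure(c(pro_close = 0, fa_atr = core[1], fa_rep = core[2],
              fa_sol = core[3], fa_pair = 0, ref = 0,
              hbond_lr_bb = 0, hbond_sr_bb = 0,
              hbond_bb_sc = core[4], hbond_sc = core[5],
              rama = 0, omega = 0),
            class = "score_breakdown")
}

# hot path: the five non-stub term values as an unnamed numeric
# (fa_atr, fa_rep, fa_sol, hbond_bb_sc, hbond_sc).  Works on squared
# distances via |r|^2 + |l|^2 - 2 r.l to stay allocation-light; called
# once per Monte Carlo step.
.surrogate_core <- function(pose, p) {
  lig <- pose$conformers[[pose$conformer]] %*% t(pose$rotation)
  nl <- nrow(lig)
  lig <- lig + rep(pose$center, each = nl)
  nr <- length(pose$rec_norm2)
  d2 <- pose$rec_norm2 - 2 * (pose$rec_xyz %*% t(lig)) +
    rep(rowSums(lig * lig), each = nr)

  cut2 <- p$lj_cutoff^2
  rmin2 <- p$lj_rmin^2
  idx <- which(d2 < cut2)
  fa_atr <- 0; fa_rep <- 0; fa_sol <- 0
  if (length(idx)) {
    # floor at ~1e-6 A so exactly overlapping atoms hit the finite cap
    # instead of producing Inf - Inf
    d2n <- pmax(d2[idx], 1e-12)
    en <- pose$rec_eps[(idx - 1L) %% nr + 1L]
    s6 <- (rmin2 / d2n)^3
    ljv <- s6 * s6 - 2 * s6
    inside <- d2n < rmin2
    fa_atr <- p$lj_depth * (sum(en[!inside] * ljv[!inside]) - sum(en[inside]))
    if (any(inside))
      fa_rep <- sum(pmin(p$rep_cap, p$lj_depth * (ljv[inside] + 1)))
    fa_sol <- p$sol_scale * sum(exp(-d2n / (2 * p$sol_sd^2)))
  }

  hb <- function(rows) {
    if (!any(rows) || !any(pose$lig_polar)) return(0)
    dd2 <- d2[rows, pose$lig_polar, drop = FALSE]
    m <- which(dd2 < cut2)
    if (!length(m)) return(0)
    ev <- pose$rec_eps[rows][(m - 1L) %% nrow(dd2) + 1L]
    dv <- sqrt(dd2[m])
    -p$hbond_depth * sum(ev * exp(-(dv - p$hbond_d0)^2 / (2 * p$hbond_sd^2)))
  }
  c(fa_atr, fa_rep, fa_sol, hb(pose$rec_polar_bb), hb(pose$rec_polar_sc))
}

#' Energy model contract
#'
#' An energy model maps a state (a pose or an abstract state such as a
#' real number or a discrete state index) to a scalar score,
#' deterministically.  Docking scores and the analytic test landscapes all
#' implement this contract.
#'
#' @param score function of one state returning a finite scalar.
#' @param breakdown optional function returning a named term breakdown.
#' @param name short label.
#' @return a list of class `energy_model`.
#' @export
energy_model <- function(score, breakdown = NULL, name = "model") {
  stopifnot(is.function(score))
  structure(list(score = score, breakdown = breakdown, name = name),
            class = "energy_model")
}

#' Surrogate full-atom energy model
#'
#' Bundles [surrogate_terms()] and [full_atom_score()] into an
#' [energy_model()]: `score(pose) = sum_i w_i s_i(pose)` (the total score,
#' "TScore", of a pose).
#'
#' @param weights a [score_weights()] vector.
#' @param params a [surrogate_params()] list.
#' @return an `energy_model` for `dock_pose` states.
#' @export
surrogate_energy_model <- function(weights = score_weights("hard"),
                                   params = surrogate_params()) {
  force(weights); force(params)
  # stub terms are identically 0, so the total reduces to the five live
  # terms; their weights are hoisted out of the per-step path (agreement
  # with full_atom_score(surrogate_terms(.)) is asserted in the tests)
  w5 <- unname(unclass(weights)[c("fa_atr", "fa_rep", "fa_sol",
                                  "hbond_bb_sc", "hbond_sc")])
  energy_model(
    score = function(pose) sum(w5 * .surrogate_core(pose, params)),
    breakdown = function(pose) surrogate_terms(pose, params),
    name = "surrogate-full-atom")
}

#' Interface-delta binding energy
#'
#' `score(bound) - score(separated)` where the separated reference is the
#' same pose with the ligand rigidly translated `separation` Angstrom away
#' along x.  Negative values indicate favourable binding.  With the
#' surrogate terms (finite cutoff) any separation of 500 Angstrom or more
#' gives the same reference.
#'
#' @param pose a [new_pose()].
#' @param model an [energy_model()] scoring `dock_pose` states.
#' @param separation rigid translation distance, Angstrom (>= 500
#'   recommended).
#' @return the scalar interface delta.
#' @export
interface_delta <- function(pose, model, separation = 500) {
  model$score(pose) - model$score(translate_pose(pose, c(separation, 0, 0)))
}
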