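# Fixture generators: analytic landscapes with closed-form Boltzmann
# behaviour and toy docking complexes with a planted binding pocket.
# Every generator is a pure function of its arguments (including the
# seed): the ambient RNG is never disturbed.

#' Discrete-state test system
#'
#' A finite state space with an energy table and a symmetric neighbour
#' proposal graph (default: complete graph).  Its exact Boltzmann
#' distribution at any temperature is available in closed form, so it
#' serves as a stationarity oracle for the Metropolis sampler.
#'
#' @param energies finite energy of each state (>= 2 states).
#' @param neighbors optional list of neighbour state indices per state;
#'   must be symmetric.  Default: all other states.
#' @return a list of class `discrete_system` with fields `model` (an
#'   [energy_model()] over state indices), `proposer`, `energies`,
#'   `n_states` and `boltzmann(T)` (the exact distribution).
#' @export
make_discrete_system <- function(energies, neighbors = NULL) {
  k <- length(energies)
  stopifnot(k >= 2, all(is.finite(energies)))
  if (is.null(neighbors))
    neighbors <- lapply(seq_len(k), function(i) setdiff(seq_len(k), i))
  stopifnot(length(neighbors) == k)
  for (i in seq_len(k)) for (j in neighbors[[i]])
    if (!(i %in% neighbors[[j]])) stop("proposal graph must be symmetric")
  force(energies)
  structure(list(
    model = energy_model(function(s) energies[s], name = "discrete"),
    proposer = function(state, local_step) {
      nb <- neighbors[[state]]
      nb[sample.int(length(nb), 1L)]
    },
    energies = energies,
    n_states = k,
    boltzmann = function(temperature) {
      w <- exp(-(energies - min(energies)) / temperature)
      w / sum(w)
    }), class = "discrete_system")
}

#' One-dimensional double-well landscape
#'
#' Quartic double well `E(x) = barrier * (x^2 - 1)^2 + asymmetry * x / 2`:
#' two minima near x = -1 (deeper for positive asymmetry) and x = +1,
#' separated by a barrier of the stated height (exact when
#' `asymmetry = 0`).  Well occupancies at any temperature follow from
#' numeric quadrature of the Boltzmann density, giving an oracle for
#' barrier-crossing and equilibration tests.
#'
#' @param barrier barrier height, energy units (> 0).
#' @param asymmetry energy offset between the wells (0 = symmetric).
#' @param step_sd Gaussian proposal standard deviation.
#' @return a list of class `double_well` with fields `model`, `proposer`,
#'   `energy(x)`, `minima()`, `occupancy_ratio(T)` (Boltzmann mass of the
#'   x > 0 well over the x < 0 well).
#' @export
make_double_well <- function(barrier, asymmetry = 0, step_sd = 0.4) {
  stopifnot(barrier > 0)
  energy <- function(x) barrier * (x^2 - 1)^2 + asymmetry * x / 2
  structure(list(
    model = energy_model(energy, name = "double-well"),
    proposer = function(state, local_step) state + rnorm(1, 0, step_sd),
    energy = energy,
    minima = function() c(optimize(energy, c(-2, 0))$minimum,
                          optimize(energy, c(0, 2))$minimum),
    occupancy_ratio = function(temperature) {
      e0 <- min(energy(-1), energy(1))
      dens <- function(x) exp(-(energy(x) - e0) / temperature)
      integrate(dens, 0, Inf)$value / integrate(dens, -Inf, 0)$value
    }), class = "double_well")
}

#' Toy-complex specification
#'
#' @param receptor_atoms pseudo-atom count of the receptor shell.
#' @param ligand_atoms ligand atom count (>= 2).
#' @param n_conformers conformer library size (conformer 1 is native).
#' @param pocket_depth attractive well-depth multiplier of pocket atoms.
#' @param background_eps multiplier of non-pocket receptor atoms.
#' @param ligand_radius ligand size: atoms are placed within this radius
#'   of the centroid, Angstrom.  Kept small so any orientation at the
#'   native centre stays within the 2 Angstrom success radius.
#' @param shell_radius receptor shell radius, Angstrom.
#' @param conformer_jitter per-atom jitter of non-native conformers,
#'   Angstrom.
#' @param start_noise s.d. of the randomised start position, Angstrom.
#' @param seed fixture seed.
#' @return a list of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(receptor_atoms = 150L, ligand_atoms = 8L,
                             n_conformers = 5L, pocket_depth = 3,
                             background_eps = 0.3, ligand_radius = 0.9,
                             shell_radius = 8, conformer_jitter = 0.25,
                             start_noise = 1.5, seed = 1L) {
  stopifnot(ligand_atoms >= 2, receptor_atoms >= 10, n_conformers >= 1)
  structure(list(receptor_atoms = as.integer(receptor_atoms),
                 ligand_atoms = as.integer(ligand_atoms),
                 n_conformers = as.integer(n_conformers),
                 pocket_depth = pocket_depth,
                 background_eps = background_eps,
                 ligand_radius = ligand_radius, shell_radius = shell_radius,
                 conformer_jitter = conformer_jitter,
                 start_noise = start_noise, seed = as.integer(seed)),
            class = "toy_complex_spec")
}

# evenly spread points on the spherical cap z/R >= cap_low (Fibonacci
# lattice restricted to the cap)
.cap_points <- function(n, radius, cap_low) {
  i <- seq_len(n) - 0.5
  z <- cap_low + (1 - cap_low) * i / n
  phi <- pi * (3 - sqrt(5)) * seq_len(n)
  r <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(r * cos(phi), r * sin(phi), z)
}

#' Generate a toy receptor-ligand complex with a planted pocket
#'
#' Builds a spherical-cap shell of receptor pseudo-atoms (opening toward
#' -z) whose atoms near the +z pole form a pocket with deepened
#' attractive wells, a compact ligand with a discrete conformer library
#' (conformer 1 native), the planted native pose (ligand centred one
#' Lennard-Jones minimum distance inside the pole), and a randomised
#' start pose outside the shell opening.  Under the shipped surrogate
#' terms the interface delta has its global minimum at the planted pose.
#'
#' @param spec a [toy_complex_spec()].
#' @return a list of class `toy_complex`: `receptor`, `conformers`,
#'   `elements`, `native_pose`, `start_pose`, `model` (surrogate
#'   full-atom model, hard weights), `spec`.
#' @export
make_toy_complex <- function(spec = toy_complex_spec()) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  s <- spec
  out <- with_stream(rng_stream(s$seed), {
    xyz <- .cap_points(s$receptor_atoms, s$shell_radius, cap_low = -0.25)
    n <- s$receptor_atoms
    backbone <- seq_len(n) %% 2L == 1L
    bb_names <- c("N", "CA", "C", "O")
    sc_names <- c("CB", "OG")
    name <- ifelse(backbone,
                   bb_names[(seq_len(n) - 1L) %/% 2L %% 4L + 1L],
                   sc_names[(seq_len(n) - 1L) %/% 2L %% 2L + 1L])
    element <- substr(sub("^([A-Z]).*", "\\1", name), 1, 1)
    role <- ifelse(backbone, "receptor-backbone", "receptor-sidechain")
    pocket <- xyz[, 3] / s$shell_radius > cos(25 * pi / 180)
    receptor <- atom_records(xyz[, 1], xyz[, 2], xyz[, 3],
                             element = element, name = name, role = role,
                             eps = ifelse(pocket, s$pocket_depth,
                                          s$background_eps))

    # compact ligand: atoms uniform in a ball, centred on the centroid
    k <- s$ligand_atoms
    dir <- matrix(rnorm(3 * k), k, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    base <- dir * (runif(k)^(1 / 3) * s$ligand_radius)
    base <- sweep(base, 2, colMeans(base))
    elements <- rep_len(c("C", "O"), k)
    conformers <- vector("list", s$n_conformers)
    conformers[[1]] <- base
    if (s$n_conformers > 1) {
      for (j in 2:s$n_conformers) {
        cf <- base + matrix(rnorm(3 * k, 0, s$conformer_jitter), k, 3)
        conformers[[j]] <- sweep(cf, 2, colMeans(cf))
      }
    }

    params <- surrogate_params()
    model <- surrogate_energy_model(score_weights("hard"), params)
    # plant the native centre at the energy optimum along the pocket axis
    # (the compromise between the Lennard-Jones and hydrogen-bond optimal
    # distances depends on the ligand's shape, so it is located here
    # rather than assumed)
    probe <- new_pose(receptor, conformers, elements, conformer = 1L,
                      rotation = diag(3), center = c(0, 0, 0))
    axial <- function(z) {
      probe$center <- c(0, 0, z)
      model$score(probe)
    }
    z_opt <- optimize(axial, c(s$shell_radius - 6, s$shell_radius - 2))$minimum
    native_pose <- new_pose(receptor, conformers, elements,
                            conformer = 1L, rotation = diag(3),
                            center = c(0, 0, z_opt))
    # start near the cavity centre: everywhere inside the shell the whole
    # inner wall is within the interaction cutoff, so the walk is guided
    # (the Lennard-Jones tail is far too weak to steer a ligand drifting
    # in free space outside the shell)
    start_center <- rnorm(3, 0, s$start_noise)
    start_pose <- new_pose(receptor, conformers, elements,
                           conformer = sample.int(s$n_conformers, 1L),
                           rotation = .uniform_rotation(),
                           center = start_center)
    list(receptor = receptor, conformers = conformers, elements = elements,
         native_pose = native_pose, start_pose = start_pose,
         model = model, spec = s)
  })
  class(out) <- "toy_complex"
  out
}

#' Constructed archive with a known Pareto-front shape
#'
#' Builds an archive table whose min-min front over (step, tscore) is
#' exactly `front_size` planted record minima; all other entries sit
#' strictly above the running record.  Optionally appends exact (x, y)
#' duplicates of existing entries (useful for tie handling tests; note
#' duplicated steps violate the strictly-increasing-step contract of the
#' replica selectors, so such tables are for [pareto_front()] tests).
#'
#' @param n number of base entries (>= 1).
#' @param seed fixture seed.
#' @param front_size planted min-min front size (<= n).
#' @param duplicate_points how many duplicate rows to append.
#' @return a data frame (class `decoy_archive`) with columns `step`,
#'   `tscore`, `replica`, `temperature`, `cycle`; planted front row
#'   indices in attribute `"front_index"`.
#' @export
make_decoy_archive <- function(n, seed = 1L, front_size = min(3L, n),
                               duplicate_points = 0L) {
  stopifnot(n >= 1, front_size >= 1, front_size <= n)
  with_stream(rng_stream(seed), {
    front_pos <- if (front_size == 1L) 1L else
      sort(c(1L, sample(2:n, front_size - 1L)))
    tscore <- numeric(n)
    record <- 10
    for (i in seq_len(n)) {
      if (i %in% front_pos) {
        record <- record - runif(1, 0.5, 1.5)
        tscore[i] <- record
      } else {
        tscore[i] <- record + runif(1, 0.1, 3)
      }
    }
    df <- data.frame(step = seq_len(n), tscore = tscore,
                     replica = rep_len(1L, n), temperature = NA_real_,
                     cycle = NA_integer_)
    if (duplicate_points > 0L) {
      dup <- df[sample.int(n, duplicate_points, replace = TRUE), , drop = FALSE]
      df <- rbind(df, dup)
    }
    rownames(df) <- NULL
    attr(df, "front_index") <- front_pos
    class(df) <- c("decoy_archive", "data.frame")
    df
  })
}
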