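# Sampling engines: Metropolis MC with Boltzmann acceptance, the
# replica-exchange main loop with even-pair neighbour swaps, and the
# multi-objective variants obtained by swapping the replica selector.

#' Geometric temperature ladder
#'
#' `numR` temperatures spanning `[minT, maxT]` with geometric spacing
#' (standard choice for roughly uniform exchange acceptance; only the
#' endpoints are prescribed).
#'
#' @param minT,maxT endpoint temperatures (`0 < minT <= maxT`).
#' @param numR number of rungs (>= 1; a single rung sits at `minT`).
#' @return numeric vector of strictly increasing temperatures.
#' @export
temperature_ladder <- function(minT, maxT, numR) {
  stopifnot(minT > 0, maxT >= minT, numR >= 1)
  if (numR == 1L) return(minT)
  if (minT == maxT) stop("exchange runs need minT < maxT")
  minT * (maxT / minT)^((0:(numR - 1)) / (numR - 1))
}

#' Sampler configuration
#'
#' The fixed reference configuration is
#' `(numR, numC, repackNth, minT, maxT) = (16, 16, 5, 2, 4)`.
#'
#' @param numR number of replicas.
#' @param numC local MC steps per replica per outer cycle.
#' @param repackNth repack-mover period (see [propose()]).
#' @param minT,maxT temperature-ladder endpoints (`minT < maxT` whenever
#'   `numR >= 2`).
#' @param seed master RNG seed; per-replica streams are derived with
#'   [derive_stream_seed()].
#' @param selector replica selector: `"last"` (REMC), `"mo"` (MO-REMC) or
#'   `"hmo"` (HMO-REMC).
#' @param n_cycles number of outer cycles.
#' @param exchange_delta_max swap rejected outright when the exchange
#'   Delta exceeds this threshold (default 75).
#' @param alternate_odd_pairs also attempt the odd rung pairs (2,3),
#'   (4,5), ... on even cycles.  Off by default: the reference scheme
#'   attempts only the even pairs (1,2), (3,4), ... every cycle, which
#'   knowingly forgoes detailed balance.
#' @param archive_mode `"global"` keeps one history archive for the whole
#'   run (selection sees all past cycles); `"cycle"` restarts the
#'   selection window each cycle.
#' @return a list of class `sampler_config`.
#' @export
sampler_config <- function(numR = 16L, numC = 16L, repackNth = 5L,
                           minT = 2, maxT = 4, seed = 1L,
                           selector = c("last", "mo", "hmo"),
                           n_cycles = 10L, exchange_delta_max = 75,
                           alternate_odd_pairs = FALSE,
                           archive_mode = c("global", "cycle")) {
  selector <- match.arg(selector)
  archive_mode <- match.arg(archive_mode)
  stopifnot(numR >= 1, numC >= 1, repackNth >= 1, n_cycles >= 1, minT > 0)
  if (numR >= 2 && !(minT < maxT))
    stop("exchange runs require minT < maxT")
  structure(list(numR = as.integer(numR), numC = as.integer(numC),
                 repackNth = as.integer(repackNth), minT = minT, maxT = maxT,
                 seed = as.integer(seed), selector = selector,
                 n_cycles = as.integer(n_cycles),
                 exchange_delta_max = exchange_delta_max,
                 alternate_odd_pairs = alternate_odd_pairs,
                 archive_mode = archive_mode),
            class = "sampler_config")
}

#' Boltzmann acceptance probability
#'
#' `exp(min(40, max(-40, (last_accepted_score - score) / T)))` with the
#' Boltzmann constant taken as 1.  The exponent clamp keeps the value
#' finite; results may exceed 1 (callers treat >= 1 as certain
#' acceptance).  Vectorised.
#'
#' @param last_accepted_score energy of the last accepted state.
#' @param score energy of the perturbed state.
#' @param temperature temperature (> 0).
#' @return probability-like scalar(s).
#' @export
boltz_acceptance_prob <- function(last_accepted_score, score, temperature) {
  if (any(temperature <= 0)) stop("temperature must be > 0")
  bf <- (last_accepted_score - score) / temperature
  exp(pmin(40, pmax(-40, bf)))
}

#' Metropolis acceptance decision
#'
#' Accepts iff the acceptance probability is >= 1 or `u` falls below it.
#' The default `"fast"` path accepts immediately whenever the Boltzmann
#' factor is non-negative, avoiding the exponential; it agrees exactly
#' with the `"exponential"` path, which evaluates
#' [boltz_acceptance_prob()] directly.  Vectorised.
#'
#' @inheritParams boltz_acceptance_prob
#' @param u uniform draw(s) in `[0, 1]`.
#' @param method `"fast"` or `"exponential"`.
#' @return logical accept flag(s).
#' @export
metropolis_accept <- function(last_accepted_score, score, temperature, u,
                              method = c("fast", "exponential")) {
  method <- match.arg(method)
  if (any(temperature <= 0)) stop("temperature must be > 0")
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  if (method == "fast") {
    bf <- (last_accepted_score - score) / temperature
    acc <- bf >= 0
    idx <- which(!acc)
    if (length(idx))
      acc[idx] <- u[pmin(length(u), idx)] < exp(pmax(-40, bf[idx]))
    acc
  } else {
    p <- boltz_acceptance_prob(last_accepted_score, score, temperature)
    p >= 1 | u < p
  }
}

#' Replica-exchange Delta
#'
#' `Delta = (beta_j - beta_i) * (E_i - E_j)` with `beta = 1/T`; the
#' product of the energy difference and inverse-temperature difference.
#' Vectorised.
#'
#' @param E_i,E_j replica energies.
#' @param T_i,T_j replica temperatures (> 0).
#' @return Delta value(s).
#' @export
exchange_delta <- function(E_i, E_j, T_i, T_j) {
  if (any(T_i <= 0) || any(T_j <= 0)) stop("temperatures must be > 0")
  (1 / T_j - 1 / T_i) * (E_i - E_j)
}

#' Replica state
#'
#' @param label replica number (travels with the pose through exchanges).
#' @param state pose (or abstract state).
#' @param energy the model's score at `state`.
#' @param temp_index rung index on the temperature ladder.
#' @param temperature temperature at that rung.
#' @return a list of class `replica_state`.
#' @export
replica_state <- function(label, state, energy, temp_index, temperature) {
  structure(list(label = label, state = state, energy = energy,
                 temp_index = temp_index, temperature = temperature),
            class = "replica_state")
}

#' Attempt a temperature exchange between two replicas
#'
#' Neighbouring rungs only.  Accepts with probability 1 when
#' `Delta <= 0`; rejects outright (without consuming `u`) when
#' `Delta > delta_max`; otherwise accepts iff `u < exp(-Delta)`.  On
#' acceptance the two replicas' rung assignments (temperatures) are
#' swapped while labels travel with the poses.
#'
#' @param rep_i,rep_j [replica_state()] objects on adjacent rungs.
#' @param u uniform draw in `[0, 1]`.
#' @param delta_max outright-rejection threshold (default 75).
#' @return list with `accepted`, `delta`, and the (possibly swapped)
#'   `rep_i`, `rep_j`.
#' @export
attempt_exchange <- function(rep_i, rep_j, u, delta_max = 75) {
  if (abs(rep_i$temp_index - rep_j$temp_index) != 1L)
    stop("exchanges are only performed between neighbouring rungs")
  d <- exchange_delta(rep_i$energy, rep_j$energy,
                      rep_i$temperature, rep_j$temperature)
  accepted <- if (d <= 0) TRUE else if (d > delta_max) FALSE else u < exp(-d)
  if (accepted) {
    ti <- rep_i$temp_index; tt <- rep_i$temperature
    rep_i$temp_index <- rep_j$temp_index
    rep_i$temperature <- rep_j$temperature
    rep_j$temp_index <- ti
    rep_j$temperature <- tt
  }
  list(accepted = accepted, delta = d, rep_i = rep_i, rep_j = rep_j)
}

# one Metropolis step; uses the ambient RNG.  Returns list(state, energy,
# accepted).  Kept internal and branch-light: this is the hot path.
.mc_step <- function(state, energy, temperature, model, proposer, local_step) {
  prop <- proposer(state, local_step)
  e_new <- model$score(prop)
  u <- runif(1)
  bf <- (energy - e_new) / temperature
  if (bf >= 0 || u < exp(max(-40, bf))) {
    list(state = prop, energy = e_new, accepted = TRUE)
  } else {
    list(state = state, energy = energy, accepted = FALSE)
  }
}

#' Metropolis Monte Carlo with Boltzmann acceptance
#'
#' Runs propose -> score -> Metropolis for `n_steps` at a fixed
#' temperature.  Every step pushes the retained sample onto the archive:
#' the perturbed conformation when accepted, otherwise a duplicate of the
#' previous accepted conformation (`accepted = FALSE`).  The final state
#' is the last accepted conformation.
#'
#' @param initial starting state (pose or abstract state).
#' @param temperature sampling temperature (> 0).
#' @param n_steps number of MC steps (>= 1).
#' @param model an [energy_model()].
#' @param proposer `function(state, local_step)` proposal, e.g.
#'   [make_pose_proposer()].
#' @param seed optional seed: the run then uses its own derived stream.
#' @param stream optional [rng_stream()] (overrides `seed`); if neither is
#'   given the ambient RNG is used.
#' @param replica_label,cycle,step_offset,local_step_offset bookkeeping
#'   used when a run is embedded in a larger schedule.
#' @param stop_fn optional early-stop check `function(archive, from)`
#'   returning `NA` or the global step at which the stop condition first
#'   holds among entries `from..end`; evaluated every `check_every` steps.
#'   Must not use the RNG.
#' @param check_every cadence of `stop_fn` checks (0 = never).
#' @return list of class `mc_result`: `final` ([replica_state()]),
#'   `archive`, `acceptance_rate`, `stopped_at` (global step or `NA`).
#' @export
mc_boltzmann <- function(initial, temperature, n_steps, model, proposer,
                         seed = NULL, stream = NULL,
                         replica_label = 1L, cycle = NA_integer_,
                         step_offset = 0L, local_step_offset = 0L,
                         stop_fn = NULL, check_every = 0L) {
  stopifnot(n_steps >= 1, temperature > 0)
  if (is.null(stream) && !is.null(seed))
    stream <- rng_stream(derive_stream_seed(seed, 1L))
  state <- initial
  energy <- model$score(initial)
  n_acc <- 0L
  n_run <- 0L
  stopped_at <- NA_integer_
  check_from <- 1L
  # archive columns as preallocated locals (in-place writes on the hot path)
  v_tscore <- numeric(n_steps)
  v_accept <- logical(n_steps)
  v_states <- vector("list", n_steps)

  view <- function(n) {
    a <- new.env(parent = emptyenv())
    a$n <- n
    a$step <- step_offset + seq_len(n)
    a$cycle <- rep(as.integer(cycle), n)
    a$replica <- rep(as.integer(replica_label), n)
    a$temperature <- rep(temperature, n)
    a$tscore <- v_tscore[seq_len(n)]
    a$accepted <- v_accept[seq_len(n)]
    a$selected <- logical(n)
    a$states <- v_states[seq_len(n)]
    class(a) <- "mc_archive"
    a
  }

  run_core <- function() {
    for (k in seq_len(n_steps)) {
      st <- .mc_step(state, energy, temperature, model, proposer,
                     local_step_offset + k)
      state <<- st$state
      energy <<- st$energy
      if (st$accepted) n_acc <<- n_acc + 1L
      v_tscore[k] <<- energy
      v_accept[k] <<- st$accepted
      v_states[[k]] <<- state
      n_run <<- k
      if (!is.null(stop_fn) && check_every > 0L && k %% check_every == 0L) {
        hit <- stop_fn(view(k), check_from)
        check_from <<- k + 1L
        if (!is.na(hit)) {
          stopped_at <<- as.integer(hit)
          break
        }
      }
    }
  }
  if (!is.null(stream)) with_stream(stream, run_core()) else run_core()

  if (!is.null(stop_fn) && is.na(stopped_at) && check_from <= n_run) {
    hit <- stop_fn(view(n_run), check_from)
    if (!is.na(hit)) stopped_at <- as.integer(hit)
  }
  structure(list(
    final = replica_state(replica_label, state, energy, 1L, temperature),
    archive = view(n_run),
    acceptance_rate = n_acc / n_run,
    stopped_at = stopped_at), class = "mc_result")
}

#' Replica-exchange Monte Carlo main loop
#'
#' Each outer cycle: (1) every replica advances `numC` Metropolis steps at
#' its current rung temperature, the replicas stepping in lockstep (step k
#' of every replica before step k+1) and pushing every retained sample
#' onto the shared history archive; (2) exchanges are attempted for the
#' even rung pairs (1,2), (3,4), ... only, with `Delta <= 0` accepted
#' outright and `Delta >` the threshold rejected without drawing a random
#' number; (3) the configured selector replaces the replica ensemble's
#' poses from the archive.  Per-cycle rung occupancy and exchange
#' statistics are recorded.
#'
#' With `selector = "last"` the selected entries are the replicas' own
#' current states and each replica simply continues (classic parallel
#' tempering).  With `"mo"`/`"hmo"` the selected poses are assigned to
#' rungs in order of increasing TScore -> increasing temperature, so the
#' lowest-energy template explores from the coldest rung.
#'
#' @param initial starting state, shared by all replicas at cycle 1.
#' @param model an [energy_model()].
#' @param proposer `function(state, local_step)` proposal.
#' @param config a [sampler_config()].
#' @param stop_fn optional early-stop check as in [mc_boltzmann()],
#'   evaluated once per cycle over that cycle's new entries.
#' @return list of class `remc_result`: `archive`, `replicas` (final
#'   [replica_state()]s), `occupancy` (cycles x replicas matrix of rung
#'   indices, recorded after the exchange sweep), `exchanges` (data frame
#'   of attempts), `ladder`, `config`, `stopped_at`.
#' @export
remc_run <- function(initial, model, proposer, config = sampler_config(),
                     stop_fn = NULL) {
  cfg <- config
  numR <- cfg$numR; numC <- cfg$numC
  ladder <- temperature_ladder(cfg$minT, cfg$maxT, numR)

  streams <- lapply(seq_len(numR), function(i)
    rng_stream(derive_stream_seed(cfg$seed, i)))
  ex_stream <- rng_stream(derive_stream_seed(cfg$seed, 0L))

  e0 <- model$score(initial)
  states <- rep(list(initial), numR)
  energies <- rep(e0, numR)
  label_rung <- seq_len(numR)        # rung currently held by each label
  local_step <- integer(numR)
  n_total <- numR * numC * cfg$n_cycles
  # archive columns as preallocated locals (in-place writes on the hot
  # path); wrapped into an mc_archive at the end / for stop_fn views
  v_replica <- integer(n_total)
  v_cycle <- integer(n_total)
  v_temp <- numeric(n_total)
  v_tscore <- numeric(n_total)
  v_accept <- logical(n_total)
  v_select <- logical(n_total)
  v_states <- vector("list", n_total)
  occupancy <- matrix(NA_integer_, cfg$n_cycles, numR)
  ex_cycle <- integer(0); ex_rung <- integer(0)
  ex_delta <- numeric(0); ex_acc <- logical(0)
  stopped_at <- NA_integer_
  gstep <- 0L

  view_window <- function(from, to) {
    w <- from:to
    a <- new.env(parent = emptyenv())
    a$n <- length(w)
    a$step <- w
    a$cycle <- v_cycle[w]
    a$replica <- v_replica[w]
    a$temperature <- v_temp[w]
    a$tscore <- v_tscore[w]
    a$accepted <- v_accept[w]
    a$selected <- v_select[w]
    a$states <- v_states[w]
    class(a) <- "mc_archive"
    a
  }
  view <- function(n) view_window(1L, n)

  ge <- globalenv()
  ambient <- if (exists(".Random.seed", envir = ge, inherits = FALSE))
    get(".Random.seed", envir = ge) else NULL
  on.exit({
    if (is.null(ambient)) {
      if (exists(".Random.seed", envir = ge, inherits = FALSE))
        rm(".Random.seed", envir = ge)
    } else assign(".Random.seed", ambient, envir = ge)
  })

  for (cycle in seq_len(cfg$n_cycles)) {
    cycle_from <- gstep + 1L
    sel_from <- if (cfg$archive_mode == "cycle") cycle_from else 1L
    for (k in seq_len(numC)) {
      for (l in seq_len(numR)) {
        assign(".Random.seed", streams[[l]]$state, envir = ge)
        local_step[l] <- local_step[l] + 1L
        st <- .mc_step(states[[l]], energies[l], ladder[label_rung[l]],
                       model, proposer, local_step[l])
        streams[[l]]$state <- get(".Random.seed", envir = ge)
        states[[l]] <- st$state
        energies[l] <- st$energy
        gstep <- gstep + 1L
        v_replica[gstep] <- l
        v_cycle[gstep] <- cycle
        v_temp[gstep] <- ladder[label_rung[l]]
        v_tscore[gstep] <- st$energy
        v_accept[gstep] <- st$accepted
        v_states[[gstep]] <- st$state
      }
    }

    # exchange sweep over even rung pairs (optionally odd pairs on even
    # cycles, a documented extension; default off)
    if (numR >= 2L) {
      lows <- seq(1L, numR - 1L, by = 2L)
      if (cfg$alternate_odd_pairs && cycle %% 2L == 0L && numR >= 3L)
        lows <- seq(2L, numR - 1L, by = 2L)
      rung_label <- integer(numR)
      rung_label[label_rung] <- seq_len(numR)
      for (r in lows) {
        li <- rung_label[r]; lj <- rung_label[r + 1L]
        d <- exchange_delta(energies[li], energies[lj],
                            ladder[r], ladder[r + 1L])
        acc <- if (d <= 0) TRUE else if (d > cfg$exchange_delta_max) FALSE else {
          assign(".Random.seed", ex_stream$state, envir = ge)
          u <- runif(1)
          ex_stream$state <- get(".Random.seed", envir = ge)
          u < exp(-d)
        }
        if (acc) {
          label_rung[li] <- r + 1L
          label_rung[lj] <- r
          rung_label[r] <- lj
          rung_label[r + 1L] <- li
        }
        ex_cycle <- c(ex_cycle, cycle); ex_rung <- c(ex_rung, r)
        ex_delta <- c(ex_delta, d); ex_acc <- c(ex_acc, acc)
      }
    }
    occupancy[cycle, ] <- label_rung

    # replica selection from the history archive
    win <- sel_from:gstep
    if (gstep - sel_from + 1L < numR)
      stop("selection window shorter than numR")
    sel_idx <- .select_indices(v_tscore[win], win, numR, cfg$selector) +
      sel_from - 1L
    v_select[sel_idx] <- TRUE
    sel_ts <- v_tscore[sel_idx]
    if (cfg$selector == "last") {
      # entries are the replicas' current states; continue each chain
      sel_lab <- v_replica[sel_idx]
      if (anyDuplicated(sel_lab))
        stop("internal error: last-numR selection did not cover all replicas")
      for (j in seq_len(numR)) {
        l <- sel_lab[j]
        states[[l]] <- v_states[[sel_idx[j]]]
        energies[l] <- sel_ts[j]
      }
    } else {
      # ascending TScore -> ascending temperature (selector output is
      # already TScore-ordered)
      labels_cold_first <- order(label_rung)
      for (j in seq_len(numR)) {
        l <- labels_cold_first[j]
        states[[l]] <- v_states[[sel_idx[j]]]
        energies[l] <- sel_ts[j]
      }
    }

    if (!is.null(stop_fn)) {
      hit <- stop_fn(view_window(cycle_from, gstep), 1L)
      if (!is.na(hit)) {
        stopped_at <- as.integer(hit)
        occupancy <- occupancy[seq_len(cycle), , drop = FALSE]
        break
      }
    }
  }

  replicas <- lapply(seq_len(numR), function(l)
    replica_state(l, states[[l]], energies[l], label_rung[l],
                  ladder[label_rung[l]]))
  structure(list(
    archive = view(gstep), replicas = replicas, occupancy = occupancy,
    exchanges = data.frame(cycle = ex_cycle, rung_low = ex_rung,
                           delta = ex_delta, accepted = ex_acc),
    ladder = ladder, config = cfg, stopped_at = stopped_at),
    class = "remc_result")
}

#' Early-stop check on archived states
#'
#' Builds a `stop_fn` for [mc_boltzmann()]/[remc_run()] that fires at the
#' first archived state satisfying `predicate` (e.g. first visit of the
#' second well, or first pose within 2 Angstrom Lrmsd of the native).
#'
#' @param predicate `function(state)` returning a logical.
#' @return a `stop_fn(archive, from)` returning the global step of the
#'   first hit among entries `from..end`, or `NA`.
#' @export
stop_when_state <- function(predicate) {
  force(predicate)
  function(archive, from) {
    n <- archive_length(archive)
    if (from > n) return(NA_integer_)
    for (i in from:n) {
      if (isTRUE(predicate(archive$states[[i]])))
        return(archive$step[i])
    }
    NA_integer_
  }
}

#' Run a sampler by method name
#'
#' Dispatches the four sampling methods.  `"mc"` runs a single Metropolis
#' chain at `minT` for `numR * numC * n_cycles` steps (equal total effort
#' to the exchange runs); the other methods run [remc_run()] with the
#' matching selector.
#'
#' @param method `"mc"`, `"remc"`, `"mo-remc"`, or `"hmo-remc"`.
#' @param initial starting state.
#' @param model an [energy_model()].
#' @param proposer proposal function.
#' @param config a [sampler_config()].
#' @param stop_fn optional early-stop check (see [mc_boltzmann()]).
#' @return an `mc_result` or `remc_result`.
#' @export
run_sampler <- function(method = c("mc", "remc", "mo-remc", "hmo-remc"),
                        initial, model, proposer, config = sampler_config(),
                        stop_fn = NULL) {
  method <- match.arg(method)
  if (method == "mc") {
    if (config$numR > 1L)
      warning("method 'mc' runs a single chain; numR > 1 and exchange ",
              "settings are ignored")
    return(mc_boltzmann(
      initial, temperature = config$minT,
      n_steps = config$numR * config$numC * config$n_cycles,
      model = model, proposer = proposer,
      stream = rng_stream(derive_stream_seed(config$seed, 1L)),
      stop_fn = stop_fn,
      check_every = if (is.null(stop_fn)) 0L else config$numC * config$numR))
  }
  config$selector <- switch(method, remc = "last", `mo-remc` = "mo",
                            `hmo-remc` = "hmo")
  remc_run(initial, model, proposer, config, stop_fn = stop_fn)
}
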