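# The history archive: a push-order queue of every retained sample with
# its global step index and score.  Pareto objectives for replica
# selection are drawn from it.

#' Create an empty sampling archive
#'
#' Entries are pushed in chronological (queue) order; `step` is the global
#' Monte Carlo step index and is strictly increasing.  Each entry records
#' the sample the chain retained at that step: the perturbed conformation
#' when the Metropolis test accepted it, otherwise a duplicate of the
#' previous accepted conformation (with `accepted = FALSE`).
#'
#' @param capacity initial capacity (grows automatically).
#' @return an object of class `mc_archive`.
#' @export
new_archive <- function(capacity = 1024L) {
  a <- new.env(parent = emptyenv())
  a$n <- 0L
  a$step <- integer(capacity)
  a$cycle <- integer(capacity)
  a$replica <- integer(capacity)
  a$temperature <- numeric(capacity)
  a$tscore <- numeric(capacity)
  a$accepted <- logical(capacity)
  a$selected <- logical(capacity)
  a$states <- vector("list", capacity)
  class(a) <- "mc_archive"
  a
}

.archive_grow <- function(a, need) {
  cap <- length(a$step)
  if (need <= cap) return(invisible(a))
  new_cap <- max(need, 2L * cap)
  length(a$step) <- new_cap
  length(a$cycle) <- new_cap
  length(a$replica) <- new_cap
  length(a$temperature) <- new_cap
  length(a$tscore) <- new_cap
  length(a$accepted) <- new_cap
  length(a$selected) <- new_cap
  length(a$states) <- new_cap
  invisible(a)
}

#' Push one entry onto an archive
#' @param a an [new_archive()].
#' @param step global MC step index (must exceed the last pushed step).
#' @param tscore energy of the retained sample.
#' @param state state snapshot (pose or abstract state).
#' @param replica replica label.
#' @param temperature temperature the sample was drawn at.
#' @param cycle outer-cycle index (`NA` for plain MC).
#' @param accepted whether the Metropolis test accepted the perturbation.
#' @return the archive, invisibly.
#' @export
archive_push <- function(a, step, tscore, state, replica = 1L,
                         temperature = NA_real_, cycle = NA_integer_,
                         accepted = TRUE) {
  n <- a$n + 1L
  .archive_grow(a, n)
  a$step[n] <- step
  a$cycle[n] <- cycle
  a$replica[n] <- replica
  a$temperature[n] <- temperature
  a$tscore[n] <- tscore
  a$accepted[n] <- accepted
  a$selected[n] <- FALSE
  a$states[[n]] <- state
  a$n <- n
  invisible(a)
}

#' Number of entries in an archive
#' @param a an `mc_archive`.
#' @return integer count.
#' @export
archive_length <- function(a) a$n

#' Archive as a data frame
#' @param a an `mc_archive` (or a data frame, returned as is).
#' @return data frame with columns `index`, `step`, `cycle`, `replica`,
#'   `temperature`, `tscore`, `accepted`, `selected`.
#' @export
archive_table <- function(a) {
  if (is.data.frame(a)) return(a)
  n <- a$n
  data.frame(index = seq_len(n), step = a$step[seq_len(n)],
             cycle = a$cycle[seq_len(n)], replica = a$replica[seq_len(n)],
             temperature = a$temperature[seq_len(n)],
             tscore = a$tscore[seq_len(n)], accepted = a$accepted[seq_len(n)],
             selected = a$selected[seq_len(n)])
}

#' State snapshots stored in an archive
#' @param a an `mc_archive`.
#' @param indices optional entry indices.
#' @return list of states.
#' @export
archive_states <- function(a, indices = NULL) {
  if (is.null(indices)) a$states[seq_len(a$n)] else a$states[indices]
}

#' @export
print.mc_archive <- function(x, ...) {
  cat(sprintf("<mc_archive> %d entries", x$n))
  if (x$n) cat(sprintf(", steps %d..%d, tscore range [%.4g, %.4g]",
                       x$step[1], x$step[x$n],
                       min(x$tscore[seq_len(x$n)]),
                       max(x$tscore[seq_len(x$n)])))
  cat("\n")
  invisible(x)
}
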