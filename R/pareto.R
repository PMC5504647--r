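# Binary-objective Pareto front and the three replica-selection
# strategies.  Objectives are (x = MC step, y = TScore); each axis can be
# independently minimised or maximised (the min-max/max-max/min-min/
# max-min scenarios).

#' Pareto dominance for two objectives
#'
#' `p` dominates `q` iff `p` is at least as good as `q` in both objectives
#' and strictly better in at least one, "better" oriented per axis by
#' `maxX`/`maxY` (`FALSE` = minimise).  A point never dominates itself.
#'
#' @param p,q length-2 numeric vectors `(x, y)`.
#' @param maxX,maxY maximise (`TRUE`) or minimise (`FALSE`) each axis.
#' @return logical.
#' @export
dominates <- function(p, q, maxX = FALSE, maxY = FALSE) {
  px <- if (maxX) -p[1] else p[1]
  qx <- if (maxX) -q[1] else q[1]
  py <- if (maxY) -p[2] else p[2]
  qy <- if (maxY) -q[2] else q[2]
  (px <= qx && py <= qy) && (px < qx || py < qy)
}

#' Binary-objective Pareto front (sweep algorithm)
#'
#' Sorts the points along objective X (orientation per `maxX`; ties broken
#' by objective Y orientation, then push order), seeds the front with the
#' first point and adds each subsequent point that is not dominated on
#' objective Y by any member already in the front.  Exact `(x, y)`
#' duplicates are collapsed to the first-pushed point before the sweep.
#' The result equals the exact non-dominated set under the flags, in
#' sweep order.
#'
#' @param points data frame with columns `x` and `y` (push order = row
#'   order), or a 2-column matrix.
#' @param maxX,maxY axis orientations (see [dominates()]).
#' @return the front as a data frame with columns `index` (row in
#'   `points`), `x`, `y`.
#' @export
pareto_front <- function(points, maxX = FALSE, maxY = FALSE) {
  if (is.matrix(points)) points <- data.frame(x = points[, 1], y = points[, 2])
  n <- nrow(points)
  if (is.null(n) || n < 1L) stop("pareto_front needs at least one point")
  x <- as.numeric(points$x)
  y <- as.numeric(points$y)
  if (any(!is.finite(y))) stop("objective values must be finite")
  keep <- !duplicated(cbind(x, y))
  idx <- which(keep)
  ox <- if (maxX) -x[idx] else x[idx]
  oy <- if (maxY) -y[idx] else y[idx]
  ord <- order(ox, oy)          # stable: push order breaks remaining ties
  idx <- idx[ord]
  oy <- oy[ord]
  best <- Inf
  on_front <- logical(length(idx))
  for (i in seq_along(idx)) {
    if (oy[i] < best) {
      on_front[i] <- TRUE
      best <- oy[i]
    }
  }
  sel <- idx[on_front]
  data.frame(index = sel, x = x[sel], y = y[sel])
}

# ---- selector internals -----------------------------------------------------

.selector_prep <- function(archive, numR) {
  df <- archive_table(archive)
  if (is.null(df$index)) df$index <- seq_len(nrow(df))
  n <- nrow(df)
  if (numR < 1L) stop("numR must be >= 1")
  if (n < numR) stop("archive has ", n, " entries; need at least numR = ", numR)
  if (n > 1L && any(diff(df$step) <= 0))
    stop("archive steps must be strictly increasing")
  df
}

# min-min front over (step, tscore) for strictly increasing steps:
# an entry is non-dominated iff its tscore is a strict running minimum.
.minmin_front_idx <- function(tscore) {
  n <- length(tscore)
  prev_min <- c(Inf, cummin(tscore)[-n])
  which(tscore < prev_min)
}

# max-min front: strict minima scanning from the most recent entry back.
.maxmin_front_idx <- function(tscore) {
  n <- length(tscore)
  suf_min <- c(rev(cummin(rev(tscore)))[-1], Inf)
  which(tscore < suf_min)
}

.fill_recent <- function(rows, n_total, need) {
  if (need <= 0L) return(integer(0))
  pool <- setdiff(rev(seq_len(n_total)), rows)
  pool[seq_len(need)]
}

# shared core of the three selectors, on raw vectors (the REMC engine
# calls this every cycle on the growing archive, so no data frames here).
# Returns row indices: push order for "last", ascending tscore (ties ->
# more recent) for "mo"/"hmo".
.select_indices <- function(tscore, step, numR, selector) {
  n <- length(tscore)
  by_ts <- function(rows) rows[order(tscore[rows], -step[rows])]
  if (selector == "last") return((n - numR + 1L):n)
  if (selector == "mo") {
    front <- .minmin_front_idx(tscore)
    rows <- if (length(front) >= numR) by_ts(front)[seq_len(numR)]
            else c(front, .fill_recent(front, n, numR - length(front)))
    return(by_ts(rows))
  }
  # hmo: fill iteratively from the two fronts' TScore-ordered sequences,
  # skipping entries already taken -- this yields their union
  u <- unique(c(by_ts(.minmin_front_idx(tscore)),
                by_ts(.maxmin_front_idx(tscore))))
  rows <- if (length(u) > numR) by_ts(u)[seq_len(numR)]
          else c(u, .fill_recent(u, n, numR - length(u)))
  by_ts(rows)
}

.selector_result <- function(df, rows) {
  out <- df[rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- the three selectors ----------------------------------------------------

#' Last-numR replica selection (classic replica exchange)
#'
#' Returns the `numR` most recently pushed archive entries, preserving
#' push order.  With the engine's interleaved push order these are the
#' current states of the `numR` replicas.
#'
#' @param archive an [new_archive()] or its [archive_table()].
#' @param numR ensemble size; the archive must hold at least `numR`
#'   entries.
#' @return data frame of the selected entries (with their `index` into
#'   the archive).
#' @export
select_remc_replicas <- function(archive, numR) {
  df <- .selector_prep(archive, numR)
  .selector_result(df, .select_indices(df$tscore, df$step, numR, "last"))
}

#' Min-min Pareto replica selection
#'
#' Computes the min-min front over (step, tscore) — the strict running
#' record minima of the score history.  If the front has at least `numR`
#' members, the `numR` of lowest TScore are returned (ties broken toward
#' the more recent entry); otherwise the whole front is completed with the
#' most recent non-front entries.  The returned set always contains the
#' archive's global TScore minimiser and is ordered by ascending TScore.
#'
#' @inheritParams select_remc_replicas
#' @return data frame of exactly `numR` selected entries.
#' @export
select_mo_remc_replicas <- function(archive, numR) {
  df <- .selector_prep(archive, numR)
  .selector_result(df, .select_indices(df$tscore, df$step, numR, "mo"))
}

#' Hybrid min-min / max-min Pareto replica selection
#'
#' Takes the union of the min-min front (record minima from the start)
#' and the max-min front (record minima scanning back from the most
#' recent entry), deduplicated by archive identity.  If the union exceeds
#' `numR`, the `numR` members of lowest TScore are kept; if it falls
#' short, the most recent remaining entries fill the ensemble.  Always
#' contains the global TScore minimiser.
#'
#' @inheritParams select_remc_replicas
#' @return data frame of exactly `numR` selected entries, ordered by
#'   ascending TScore.
#' @export
select_hmo_remc_replicas <- function(archive, numR) {
  df <- .selector_prep(archive, numR)
  .selector_result(df, .select_indices(df$tscore, df$step, numR, "hmo"))
}

#' Look up a selector by name
#' @param selector `"last"`, `"mo"`, or `"hmo"`.
#' @return the selector function.
#' @export
replica_selector <- function(selector = c("last", "mo", "hmo")) {
  switch(match.arg(selector),
         last = select_remc_replicas,
         mo = select_mo_remc_replicas,
         hmo = select_hmo_remc_replicas)
}
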