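# Replayable RNG streams.  Each replica owns one stream so results are
# bit-identical no matter in which order replicas are advanced between
# exchange points (the serial run reproduces a parallel schedule).

#' Derive a child seed from a master seed
#'
#' Deterministic scheme used to give every replica (and the exchange sweep)
#' its own independent stream: `(master * 48271 + k * 1000003) mod (2^31-1)`.
#' All arithmetic stays exact in doubles.
#'
#' @param master_seed integer master seed of the run.
#' @param k stream index (0 = exchange stream, 1..numR = replicas).
#' @return an integer seed in `[0, 2^31-1)`.
#' @export
derive_stream_seed <- function(master_seed, k) {
  s <- (as.double(master_seed) %% 2147483647) * 48271 + as.double(k) * 1000003
  as.integer(s %% 2147483647)
}

#' Create an independent RNG stream
#'
#' A stream is a saved `.Random.seed` state.  Code run under
#' [with_stream()] draws from (and advances) that state without disturbing
#' the ambient RNG.
#'
#' @param seed integer seed for the stream.
#' @return an object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  ge <- globalenv()
  old <- if (exists(".Random.seed", envir = ge, inherits = FALSE))
    get(".Random.seed", envir = ge) else NULL
  set.seed(seed)
  e$state <- get(".Random.seed", envir = ge)
  if (is.null(old)) {
    rm(".Random.seed", envir = ge)
  } else {
    assign(".Random.seed", old, envir = ge)
  }
  class(e) <- "rng_stream"
  e
}

#' Evaluate an expression under an RNG stream
#'
#' Swaps the stream's state into `.Random.seed`, evaluates `expr` in the
#' caller's frame, then saves the advanced state back into the stream and
#' restores the ambient RNG.
#'
#' @param stream an [rng_stream()].
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_stream <- function(stream, expr) {
  ge <- globalenv()
  old <- if (exists(".Random.seed", envir = ge, inherits = FALSE))
    get(".Random.seed", envir = ge) else NULL
  assign(".Random.seed", stream$state, envir = ge)
  on.exit({
    stream$state <- get(".Random.seed", envir = ge)
    if (is.null(old)) {
      if (exists(".Random.seed", envir = ge, inherits = FALSE))
        rm(".Random.seed", envir = ge)
    } else {
      assign(".Random.seed", old, envir = ge)
    }
  })
  expr
}
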