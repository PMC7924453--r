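# Named random substreams.  Every stochastic draw in the simulator reduces to
# uniforms pulled from one of these streams, so the full event trace is a
# deterministic function of (master seed, replication index).

STREAM_NAMES <- c("arrivals", "attributes", "durations", "exams",
                  "consults", "routing")

#' Create named random substreams
#'
#' Builds a set of independent uniform-deviate streams, one per named source of
#' randomness in the simulator (arrivals, patient attributes, task durations,
#' exams, consults, routing).  Each substream is seeded deterministically from
#' the master seed and replication index, so an identical
#' `(seed, replication)` pair reproduces the event trace bit for bit.
#'
#' @param seed master integer seed.
#' @param replication replication index (1-based).
#' @param names character vector of substream names.
#' @return an object of class `ed_streams`: a named list of stream
#'   environments usable with [stream_runif()].
#' @export
ed_streams <- function(seed, replication = 1L, names = STREAM_NAMES) {
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed), replication >= 1L)
  streams <- lapply(seq_along(names), function(i) {
    # distinct large-prime mixing keeps substreams well separated
    sub <- (as.double(seed) * 48271 + as.double(replication) * 104729 +
              i * 7919) %% 2147483629
    e <- new.env(parent = emptyenv())
    e$seed_val <- as.integer(sub)
    e$state <- NULL   # lazily initialised .Random.seed snapshot
    e$buf <- numeric(0)
    e$pos <- 0L
    e
  })
  names(streams) <- names
  class(streams) <- "ed_streams"
  streams
}

# refill the stream's uniform buffer, swapping .Random.seed in and out
stream_refill <- function(s, n = 4096L) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  if (is.null(s$state)) {
    set.seed(s$seed_val)
  } else {
    assign(".Random.seed", s$state, envir = globalenv())
  }
  s$buf <- stats::runif(n)
  s$pos <- 0L
  s$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(s)
}

#' Draw uniforms from a substream
#'
#' @param s one element of an [ed_streams()] set.
#' @param n number of U(0,1) deviates.
#' @return numeric vector of length `n`.
#' @export
stream_runif <- function(s, n = 1L) {
  if (n == 1L) {               # fast path: single deviate
    if (s$pos >= length(s$buf)) stream_refill(s)
    s$pos <- s$pos + 1L
    return(s$buf[[s$pos]])
  }
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    if (s$pos >= length(s$buf)) stream_refill(s, max(4096L, n - got))
    take <- min(length(s$buf) - s$pos, n - got)
    out[(got + 1L):(got + take)] <- s$buf[(s$pos + 1L):(s$pos + take)]
    s$pos <- s$pos + take
    got <- got + take
  }
  out
}
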