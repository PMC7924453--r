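# Duration distributions used by the care-pathway task table.  All sampling is
# inverse-CDF on substream uniforms (see streams.R) so draws are reproducible
# and stream-independent.

#' Triangular distribution specification
#'
#' @param low,mode,high minutes, with `low <= mode <= high`.
#' @return a duration spec usable in task tables.
#' @examples
#' dist_tri(4, 7, 10)   # triage duration
#' @export
dist_tri <- function(low, mode, high) {
  stopifnot(low <= mode, mode <= high, low >= 0)
  structure(list(kind = "tri", low = low, mode = mode, high = high),
            class = "ed_dist")
}

#' Constant duration specification
#' @param value minutes (> 0 unless explicitly a zero placeholder).
#' @export
dist_const <- function(value) {
  stopifnot(value >= 0)
  structure(list(kind = "const", value = value), class = "ed_dist")
}

#' CTAS-conditional constant duration
#'
#' One constant per acuity level, e.g. the nurse assessment
#' (CTAS IV/V: 5, III: 10, II: 15 minutes).
#' @param values named numeric vector with names among `I,II,III,IV,V`.
#' @export
dist_ctas <- function(values) {
  stopifnot(all(names(values) %in% c("I", "II", "III", "IV", "V")))
  structure(list(kind = "ctas", values = values), class = "ed_dist")
}

#' Two-point mixture duration
#'
#' e.g. disposition: 30 min with probability 0.2, else 3 min.
#' @param p probability of the first branch.
#' @param first,second branch durations in minutes.
#' @export
dist_mix <- function(p, first, second) {
  stopifnot(p >= 0, p <= 1)
  structure(list(kind = "mix", p = p, first = first, second = second),
            class = "ed_dist")
}

#' Continuous uniform duration
#' @param min,max minutes.
#' @export
dist_unif <- function(min, max) {
  stopifnot(min <= max)
  structure(list(kind = "unif", min = min, max = max), class = "ed_dist")
}

# inverse CDF of the triangular distribution
qtri <- function(u, low, mode, high) {
  fc <- if (high > low) (mode - low) / (high - low) else 0
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

#' Sample a task duration
#'
#' Draws one duration (minutes) from a duration spec.  Triangular draws use
#' the inverse CDF; CTAS-conditional constants are returned exactly.
#'
#' @param dist an `ed_dist` spec.
#' @param stream substream supplying uniforms (constants consume none).
#' @param ctas patient acuity, required for CTAS-conditional specs.
#' @return duration in minutes.
#' @export
sample_duration <- function(dist, stream = NULL, ctas = NULL) {
  switch(dist$kind,
    const = dist$value,
    ctas = {
      if (is.null(ctas) || !ctas %in% names(dist$values))
        stop("duration not defined for CTAS level ", ctas)
      unname(dist$values[[ctas]])
    },
    tri = qtri(stream_runif(stream), dist$low, dist$mode, dist$high),
    unif = dist$min + stream_runif(stream) * (dist$max - dist$min),
    mix = if (stream_runif(stream) < dist$p) dist$first else dist$second,
    stop("unknown duration kind: ", dist$kind)
  )
}

#' Mean of a duration spec
#'
#' Closed-form expectation; used by the sizing heuristic and in tests.
#' @inheritParams sample_duration
#' @export
dist_mean <- function(dist, ctas = NULL) {
  switch(dist$kind,
    const = dist$value,
    ctas = if (is.null(ctas)) mean(dist$values) else unname(dist$values[[ctas]]),
    tri = (dist$low + dist$mode + dist$high) / 3,
    unif = (dist$min + dist$max) / 2,
    mix = dist$p * dist$first + (1 - dist$p) * dist$second
  )
}
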