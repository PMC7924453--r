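# Arrival-rate surface: expected patients per (weekday, 2-hour bin, CTAS
# level), repeated weekly, driving a piecewise-constant-rate Poisson arrival
# process.  A rate table comes from a CSV or from the synthetic weekly
# profile generator.

WEEKDAYS <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
BIN_STARTS <- seq(0, 22, by = 2)          # hours; half-open 2 h bins

#' Construct an arrival-rate table
#'
#' @param rates numeric array `[7 weekday, 12 bin, 5 ctas]` of expected
#'   arrivals per two-hour bin.
#' @return object of class `ed_rate_table`.
#' @export
ed_rate_table <- function(rates) {
  stopifnot(is.array(rates), all(dim(rates) == c(7L, 12L, 5L)))
  if (any(rates < 0)) stop("arrival rates must be non-negative")
  dimnames(rates) <- list(WEEKDAYS, sprintf("%02d:00", BIN_STARTS), CTAS_LEVELS)
  structure(rates, class = "ed_rate_table")
}

#' @export
print.ed_rate_table <- function(x, ...) {
  cat("Arrival-rate table: weekly total", round(sum(x), 1), "patients\n")
  byday <- apply(unclass(x), 1, sum)
  cat("  by weekday:", paste(names(byday), round(byday, 1)), "\n")
  bymix <- apply(unclass(x), 3, sum) / sum(x)
  cat("  CTAS mix:", paste(names(bymix), sprintf("%.1f%%", 100 * bymix)), "\n")
  invisible(x)
}

#' Read an arrival-rate table from CSV
#'
#' Expected columns: `weekday` (Mon..Sun), `bin_start` (HH:MM, even hours),
#' `ctas` (I..V), `rate` (patients per bin, >= 0).  Cells absent from the file
#' default to 0 with a warning.
#'
#' @param path CSV file path.
#' @return an [ed_rate_table()].
#' @export
read_rate_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("weekday", "bin_start", "ctas", "rate")
  if (!all(need %in% names(d)))
    stop("rate CSV must have columns: ", paste(need, collapse = ", "))
  bad <- which(d$rate < 0)
  if (length(bad))
    stop("negative rate in row ", bad[1], " of ", path)
  if (!all(d$ctas %in% CTAS_LEVELS))
    stop("unknown CTAS label: ", paste(setdiff(d$ctas, CTAS_LEVELS), collapse = ", "))
  if (!all(d$weekday %in% WEEKDAYS))
    stop("unknown weekday: ", paste(setdiff(d$weekday, WEEKDAYS), collapse = ", "))
  hours <- as.integer(sub(":.*", "", d$bin_start))
  if (!all(hours %in% BIN_STARTS))
    stop("bin_start must be an even hour HH:MM, got: ",
         paste(unique(d$bin_start[!hours %in% BIN_STARTS]), collapse = ", "))
  r <- array(0, dim = c(7L, 12L, 5L))
  i <- cbind(match(d$weekday, WEEKDAYS), match(hours, BIN_STARTS),
             match(d$ctas, CTAS_LEVELS))
  r[i] <- d$rate
  if (nrow(d) < 420L)
    warning(420L - nrow(unique(as.data.frame(i))),
            " rate cells missing from ", path, "; defaulting to 0")
  ed_rate_table(r)
}

#' Write an arrival-rate table to CSV
#' @param table an [ed_rate_table()].
#' @param path output file.
#' @export
write_rate_table <- function(table, path) {
  g <- expand.grid(weekday = WEEKDAYS, bin = BIN_STARTS, ctas = CTAS_LEVELS,
                   stringsAsFactors = FALSE)
  d <- data.frame(weekday = g$weekday,
                  bin_start = sprintf("%02d:00", g$bin),
                  ctas = g$ctas,
                  rate = as.vector(unclass(table)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Synthetic weekly arrival profile
#'
#' Emulates the structure of the study ED's arrival data: roughly 1,504
#' patients per week, rates rising from 08:00 with a peak in the 10:00-12:00
#' bin, Tuesday-Thursday the busiest days, and CTAS III/IV predominant.  The
#' default weight vectors are documented modelling assumptions; a real rate
#' CSV replaces the whole table.
#'
#' @param weekly_total expected patients per week.
#' @param ctas_mix length-5 proportions (CTAS I..V), summing to 1.
#' @param weekday_weights length-7 proportions (Mon..Sun), summing to 1.
#' @param diurnal_shape length-12 bin weights (00:00..22:00), summing to 1.
#' @return a `ed_profile_spec` list.
#' @export
ed_profile_spec <- function(weekly_total = 1504,
                            ctas_mix = c(0.02, 0.13, 0.40, 0.35, 0.10),
                            weekday_weights =
                              c(1, 1.2, 1.2, 1.2, 1, 0.8, 0.8) / 7.2,
                            diurnal_shape = default_diurnal_shape()) {
  stopifnot(weekly_total > 0, length(ctas_mix) == 5,
            length(weekday_weights) == 7, length(diurnal_shape) == 12)
  for (w in list(ctas_mix, weekday_weights, diurnal_shape))
    if (abs(sum(w) - 1) > 1e-9)
      stop("proportion vectors must sum to 1")
  structure(list(weekly_total = weekly_total, ctas_mix = ctas_mix,
                 weekday_weights = weekday_weights,
                 diurnal_shape = diurnal_shape),
            class = "ed_profile_spec")
}

# unimodal within-day shape: overnight trough, climb from 08:00, peak 10:00-12:00
default_diurnal_shape <- function() {
  s <- c(3.0, 2.0, 1.5, 2.0, 9.0, 14.0, 13.0, 12.0, 11.0, 10.0, 8.0, 5.0)
  s / sum(s)
}

#' Build a rate table from a synthetic profile
#'
#' `rate[d, b, c] = weekly_total * weekday[d] * diurnal[b] * ctas[c]`.
#'
#' @param spec an [ed_profile_spec()].
#' @return an [ed_rate_table()] whose grand total equals `weekly_total`.
#' @export
build_synthetic_table <- function(spec = ed_profile_spec()) {
  stopifnot(inherits(spec, "ed_profile_spec"))
  r <- spec$weekly_total *
    outer(outer(spec$weekday_weights, spec$diurnal_shape), spec$ctas_mix)
  ed_rate_table(array(r, dim = c(7L, 12L, 5L)))
}

#' Sample arrival times from a rate table
#'
#' Piecewise-constant-rate Poisson process: per (weekday, bin, CTAS) cell the
#' arrival count is Poisson with mean `scale * rate`, and arrival instants are
#' uniform within the two-hour bin.  The weekly surface repeats for horizons
#' beyond one week.
#'
#' @param table an [ed_rate_table()].
#' @param scale arrival-rate multiplier in (0, 1] (demand sensitivity knob).
#' @param horizon minutes from the Monday 00:00 origin.
#' @param stream uniform substream (see [ed_streams()]).
#' @return data.frame with `time` (minutes, sorted) and `ctas`.
#' @export
sample_arrival_times <- function(table, scale = 1, horizon, stream) {
  stopifnot(inherits(table, "ed_rate_table"), scale > 0, horizon > 0)
  rates <- unclass(table)
  out_t <- numeric(0); out_c <- character(0)
  week <- 0L
  repeat {
    week_start <- week * 10080
    if (week_start >= horizon) break
    for (d in 1:7) for (b in 1:12) {
      bin_start <- week_start + (d - 1) * 1440 + (b - 1) * 120
      if (bin_start >= horizon) next
      for (cc in 1:5) {
        lam <- scale * rates[d, b, cc]
        if (lam <= 0) next
        n <- stats::qpois(stream_runif(stream), lam)
        if (n > 0) {
          tt <- bin_start + 120 * stream_runif(stream, n)
          keep <- tt < horizon
          out_t <- c(out_t, tt[keep])
          out_c <- c(out_c, rep(CTAS_LEVELS[cc], sum(keep)))
        }
      }
    }
    week <- week + 1L
  }
  o <- order(out_t)
  data.frame(time = out_t[o], ctas = out_c[o], stringsAsFactors = FALSE)
}

#' Sample treatment categories
#'
#' Draws from the packaged category mix (printed shares renormalised to 1).
#'
#' @param stream uniform substream.
#' @param n number of draws.
#' @param categories category table, see [ed_categories()].
#' @return character vector of category codes.
#' @export
sample_category <- function(stream, n = 1L, categories = ed_categories()) {
  u <- stream_runif(stream, n)
  cum <- cumsum(categories$prop)
  categories$category[findInterval(u, cum) + 1L]
}

#' Sample arrival mode
#'
#' Bernoulli ambulance indicator; ambulance patients skip registration and are
#' triaged through the EHS tasks.
#'
#' @param stream uniform substream.
#' @param p_ems ambulance probability in `[0, 1]`.
#' @param n number of draws.
#' @return character vector, `"walk-in"` or `"ambulance"`.
#' @export
assign_mode <- function(stream, p_ems, n = 1L) {
  stopifnot(p_ems >= 0, p_ems <= 1)
  ifelse(stream_runif(stream, n) < p_ems, "ambulance", "walk-in")
}
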