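# Specialist consult layer: rosters with availability windows, response
# delays, internal-medicine coverage, and the specialist queue discipline.

#' Default specialist roster
#'
#' One specialist per specialty.  The urologist, gynecologist,
#' otolaryngologist and ophthalmologist work 08:00-17:00; the cardiologist and
#' gastroenterologist share that window but are covered by Internal Medicine
#' outside it; everyone else operates all hours.  Response delays: psychiatrist
#' 1-6 h (uniform), neurologist 15-90 min graded by CTAS level, Crisis
#' Response about 5 min; other specialties incur only window waiting.
#'
#' @param fp if `TRUE`, applies the final-planning changes: psychiatrist and
#'   Crisis Response on site around the clock (one each, zero delay) and the
#'   neurologist on site during the 08:00-17:00 window (zero delay); otherwise
#'   the initial-planning roster (two Crisis Response 08:30-19:30, specialists
#'   off site).
#' @return data.frame roster, one row per specialty.
#' @export
ed_specialist_roster <- function(fp = FALSE) {
  r <- data.frame(
    name = c("Respiratory Therapist", "Gastroenterologist", "Orthopedist",
             "Cardiologist", "Dermatologist", "Urologist", "Otolaryngologist",
             "Crisis Response", "Neurologist", "Ophthalmologist",
             "Gynecologist", "Psychiatrist", "Internal Medicine"),
    count = 1L,
    window_start = 0,       # minutes of day; 0/1440 = all hours
    window_end = 1440,
    delay = "none",         # response-delay rule
    covered_by = NA_character_,
    on_site = FALSE,
    stringsAsFactors = FALSE)
  rownames(r) <- r$name
  win <- function(who, s, e) {
    r[who, "window_start"] <<- s * 60; r[who, "window_end"] <<- e * 60
  }
  win("Urologist", 8, 17); win("Gynecologist", 8, 17)
  win("Otolaryngologist", 8, 17); win("Ophthalmologist", 8, 17)
  win("Cardiologist", 8, 17); win("Gastroenterologist", 8, 17)
  r["Cardiologist", "covered_by"] <- "Internal Medicine"
  r["Gastroenterologist", "covered_by"] <- "Internal Medicine"
  r["Psychiatrist", "delay"] <- "psychiatrist"
  r["Neurologist", "delay"] <- "neurologist"
  r["Crisis Response", "delay"] <- "crisis"
  if (fp) {
    r["Psychiatrist", "on_site"] <- TRUE
    r["Crisis Response", "on_site"] <- TRUE   # one around the clock
    r["Neurologist", "on_site"] <- TRUE       # on site inside 08:00-17:00
    win("Neurologist", 8, 17)
  } else {
    r["Crisis Response", "count"] <- 2L
    r["Crisis Response", c("window_start", "window_end")] <-
      c(8.5 * 60, 19.5 * 60)
  }
  r
}

#' Consult demand for a patient
#'
#' First-consult probability and duration come from the packaged consult
#' table for the patient's category and CTAS group; a second consult is
#' supported but defaults to probability 0.
#'
#' @param ctas,category patient profile.
#' @param stream uniform substream.
#' @param consults consult table, see [ed_consults()].
#' @param p_second probability of a second (independent, same-table) consult.
#' @return list of consults, each `list(specialist, duration_min)`;
#'   empty when no consult is drawn (always for GMI and ARV).
#' @export
needs_consult <- function(ctas, category, stream, consults = ed_consults(),
                          p_second = 0) {
  spec <- consults[[category]]
  if (is.null(spec)) return(list())
  g <- ctas_group(ctas)
  out <- list()
  n_try <- 1L + (p_second > 0 && stream_runif(stream) < p_second)
  for (i in seq_len(n_try)) {
    if (stream_runif(stream) < spec$prob[[g]]) {
      dur <- sample_duration(spec$duration[[g]], stream, ctas)
      out[[length(out) + 1L]] <- list(specialist = spec$specialist,
                                      duration = dur)
    }
  }
  out
}

# response delay in minutes for a roster row
specialist_response_delay <- function(rule, ctas, stream) {
  switch(rule,
    none = 0,
    crisis = 5,
    psychiatrist = 60 + stream_runif(stream) * 300,
    # 15..90 min graded by acuity: I fastest, V slowest
    neurologist = 15 + (match(ctas, CTAS_LEVELS) - 1) / 4 * 75,
    stop("unknown delay rule: ", rule))
}

#' Resolve who serves a consult call and when they reach the patient
#'
#' Inside the availability window the named specialist serves after their
#' response delay; outside it, the covering service (Internal Medicine for
#' cardiology/nephrology/gastroenterology) takes over immediately, and
#' specialties without coverage wait for the next window start.  On-site
#' specialists have zero response delay.
#'
#' @param roster roster data.frame ([ed_specialist_roster()]).
#' @param specialist specialty name.
#' @param ctas patient CTAS level (grades the neurologist delay).
#' @param call_time minutes since the Monday 00:00 origin.
#' @param stream uniform substream.
#' @return list `(server, arrival)`: the serving specialty and the earliest
#'   minute the specialist reaches the patient (`arrival >= call_time`).
#' @export
specialist_arrival_time <- function(roster, specialist, ctas, call_time,
                                    stream) {
  row <- roster[roster$name == specialist, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown specialist: ", specialist)
  tod <- call_time %% 1440
  in_window <- tod >= row$window_start && tod < row$window_end
  if (!in_window && row$window_start == 0 && row$window_end == 1440)
    in_window <- TRUE
  if (!in_window) {
    if (!is.na(row$covered_by))
      return(list(server = row$covered_by, arrival = call_time))
    # wait for the next window start (possibly tomorrow)
    day0 <- call_time - tod
    start <- day0 + row$window_start
    if (tod >= row$window_start) start <- start + 1440
    call_time <- start
  }
  delay <- if (row$on_site) 0 else
    specialist_response_delay(row$delay, ctas, stream)
  list(server = row$name, arrival = call_time + delay)
}

#' Specialist queue discipline
#'
#' An arrived specialist attends waiting patients in ascending CTAS order
#' (level I first), first-come-first-served within a level.
#'
#' @param ctas character vector of waiting patients' CTAS levels.
#' @param request_time numeric vector of their request times.
#' @return integer permutation giving the service order.
#' @export
consult_queue_order <- function(ctas, request_time = seq_along(ctas)) {
  order(match(ctas, CTAS_LEVELS), request_time)
}
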