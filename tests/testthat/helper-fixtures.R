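# Shared fixtures: all built in code at test time.

# a rate table putting `rate` in every CTAS-III cell and 0 elsewhere
ctas3_table <- function(rate = 0.5) {
  r <- array(0, dim = c(7, 12, 5))
  r[, , 3] <- rate
  ed_rate_table(r)
}

# collapse every triangular/uniform/mixture duration to a constant so the
# pathway becomes deterministic given the routing draws
collapse_tasks <- function(tasks) {
  lapply(tasks, function(t) {
    d <- t$duration
    t$duration <- switch(d$kind,
      tri = dist_const(d$mode),
      unif = dist_const((d$min + d$max) / 2),
      d)
    t
  })
}

# scenario with effectively infinite capacity everywhere, no exams, no
# consults, no ambulances, no briefings: patients never wait
freeflow_scenario <- function(..., arrivals = ctas3_table(0.5)) {
  big <- shift_schedule(c("00:00-00:00" = 500))
  staffing <- stats::setNames(rep(list(big), length(edflow:::STAFF_ROLES)),
                              edflow:::STAFF_ROLES)
  cat0 <- ed_categories()
  cat0$prop <- ifelse(cat0$category == "GMI", 1, 0)   # GMI: no specialist
  roster <- ed_specialist_roster(fp = TRUE)
  roster$count <- 500L
  defaults <- list(
    locations = c(BA = 10000, MBA = 10000, VA = 10000, SSU = 10000),
    staffing = staffing,
    arrivals = arrivals,
    p_ems = 0,
    categories = cat0,
    exam_probs = ed_exam_probs() * 0,
    specialists = roster,
    global_tasks = FALSE,
    replications = 1)
  do.call(ed_scenario, utils::modifyList(defaults, list(...)))
}

# tiny congested scenario for queueing/monotonicity behaviour at low cost
small_scenario <- function(...) {
  defaults <- list(arrivals = ed_profile_spec(weekly_total = 300),
                   horizon = 4320, warmup = 1440, replications = 1)
  do.call(ed_scenario, utils::modifyList(defaults, list(...)))
}

new_test_stream <- function(seed = 1) ed_streams(seed)$attributes
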