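# Replication engine: wires the care pathway onto the event-calendar kernel.
# One replication simulates Monday 00:00 to the horizon (default the
# following-week Tuesday, 8 days); statistics are collected on the
# warm-up-to-horizon window with patients attributed by arrival time.

ctas_num <- function(ctas) match(ctas, CTAS_LEVELS)

# resolve task staff names ("EDN" -> patient's team) to pool-need vectors
staff_needs <- function(staff, team) {
  if (length(staff) == 0) return(integer(0))
  staff[staff == "EDN"] <- team
  n <- rep(1L, length(staff))
  names(n) <- staff
  n
}

# begin a task: seize its staff (or run unstaffed), continue at `next_stage`
begin_task <- function(sim, p, task_name, next_stage,
                       duration = NULL, also_release = NULL) {
  spec <- sim$scn$tasks[[task_name]]
  if (is.null(spec)) stop("unknown task: ", task_name)
  needs <- staff_needs(spec$staff, if (is.null(p)) "EDN2" else p$team)
  tag <- list(kind = "task", task = task_name, patient = p,
              next_stage = next_stage, duration = duration,
              also_release = also_release)
  if (length(needs) == 0) {
    dur <- if (!is.null(duration)) duration else
      sample_duration(spec$duration, sim$streams$durations,
                      if (!is.null(p)) p$ctas else NULL)
    schedule_event(sim, sim$clock + dur, "task_end",
                   list(needs = integer(0), tag = tag, dur = dur))
  } else {
    seize(sim, needs, if (is.null(p)) 3 else ctas_num(p$ctas), tag)
  }
  invisible(NULL)
}

# pure delay (exam turnaround, specialist travel)
begin_delay <- function(sim, p, minutes, next_stage) {
  schedule_event(sim, sim$clock + minutes, "delay_end",
                 list(patient = p, next_stage = next_stage, dur = minutes))
}

engine_on_grant <- function(sim, req) {
  tag <- req$tag
  t <- sim$clock
  switch(tag$kind,
    task = {
      p <- tag$patient
      spec <- sim$scn$tasks[[tag$task]]
      dur <- if (!is.null(tag$duration)) tag$duration else
        sample_duration(spec$duration, sim$streams$durations,
                        if (!is.null(p)) p$ctas else NULL)
      if (!is.null(p)) {
        if (tag$task == "physician_assessment" && is.na(p$first_physician))
          p$first_physician <- t
        if (tag$task == "transport_to_ssu") {
          # the ED bed frees at transport start; room turnover blocks it
          schedule_event(sim, t, "free_bed",
                         list(area = p$area, team = p$team,
                              prio = ctas_num(p$ctas)))
        }
      }
      schedule_event(sim, t + dur, "task_end",
                     list(needs = req$needs, tag = tag, dur = dur))
    },
    bed = {
      p <- tag$patient
      p$bed_assigned <- t
      advance_patient(sim, p, "escort")
    },
    ssu_bed = {
      p <- tag$patient
      begin_task(sim, p, "transport_to_ssu", "ssu_arrive")
    },
    consult = {
      p <- tag$patient
      dur <- tag$duration
      schedule_event(sim, t + dur, "task_end",
                     list(needs = req$needs,
                          tag = list(kind = "task", task = "consult",
                                     patient = p,
                                     next_stage = "consult_discuss"),
                          dur = dur))
    },
    global = {
      schedule_event(sim, t + tag$duration, "global_end",
                     list(needs = req$needs))
    },
    stop("unknown grant tag: ", tag$kind)
  )
}

advance_patient <- function(sim, p, stage) {
  scn <- sim$scn
  switch(stage,
    start = {
      if (p$mode == "ambulance") begin_task(sim, p, "ehs_call", "ehs_triage")
      else begin_task(sim, p, "triage", "register")
    },
    ehs_triage = begin_task(sim, p, "ehs_triage", "want_bed"),
    register = begin_task(sim, p, "register_patient", "want_bed"),
    want_bed = {
      mba <- sim$pools$MBA
      mba_full <- is.null(mba) || mba$busy >= pool_capacity(mba, sim$clock)
      p$area <- area_for(p$ctas, p$category, mba_full)
      needs <- 1L; names(needs) <- p$area
      seize(sim, needs, ctas_num(p$ctas), list(kind = "bed", patient = p))
    },
    escort = begin_task(sim, p, "escort_to_bed", "nurse_assess"),
    nurse_assess = begin_task(sim, p, "nurse_assessment", "phys_assess"),
    phys_assess = begin_task(sim, p, "physician_assessment", "write_orders"),
    write_orders = begin_task(sim, p, "write_orders", "exams_start"),
    exams_start = {
      if (length(p$exams) > 0) begin_task(sim, p, "initiate_di_lab", "exam_next")
      else advance_patient(sim, p, "procedure")
    },
    exam_next = {
      if (p$exam_idx > length(p$exams)) {
        begin_task(sim, p, "review_tests_nurse", "review_phys")
      } else {
        exam <- p$exams[p$exam_idx]
        if (exam %in% DI_EXAMS) begin_task(sim, p, "prepare_for_di", "exam_out")
        else begin_task(sim, p, "take_specimen", "exam_wait_lab")
      }
    },
    exam_out = {
      exam <- p$exams[p$exam_idx]
      esc <- staff_needs(escort_requirement(p$ctas, exam), p$team)
      dur <- sample_duration(scn$transport_leg, sim$streams$durations)
      seize(sim, esc, ctas_num(p$ctas),
            list(kind = "task", task = "di_leg", patient = p,
                 next_stage = "exam_wait_di", duration = dur))
    },
    exam_wait_di = begin_delay(sim, p,
      sample_duration(scn$turnaround_imaging, sim$streams$exams), "exam_back"),
    exam_back = {
      exam <- p$exams[p$exam_idx]
      esc <- staff_needs(escort_requirement(p$ctas, exam), p$team)
      dur <- sample_duration(scn$transport_leg, sim$streams$durations)
      seize(sim, esc, ctas_num(p$ctas),
            list(kind = "task", task = "di_leg", patient = p,
                 next_stage = "exam_receive", duration = dur))
    },
    exam_wait_lab = begin_delay(sim, p,
      sample_duration(scn$turnaround_lab, sim$streams$exams), "exam_receive"),
    exam_receive = begin_task(sim, p, "receive_tests", "exam_done"),
    exam_done = {
      p$exam_idx <- p$exam_idx + 1L
      advance_patient(sim, p, "exam_next")
    },
    review_phys = begin_task(sim, p, "review_tests_physician", "procedure"),
    procedure = {
      if (isTRUE(p$procedure))
        begin_task(sim, p, "medical_procedure", "consult_start")
      else advance_patient(sim, p, "consult_start")
    },
    consult_start = {
      if (p$consult_idx > length(p$consults))
        advance_patient(sim, p, "disposition")
      else begin_task(sim, p, "initiate_consult", "consult_arrange")
    },
    consult_arrange = begin_task(sim, p, "arrange_consultant", "consult_contact"),
    consult_contact = begin_task(sim, p, "contact_specialist", "consult_call"),
    consult_call = {
      cons <- p$consults[[p$consult_idx]]
      res <- specialist_arrival_time(scn$specialists, cons$specialist,
                                     p$ctas, sim$clock, sim$streams$consults)
      p$consult_server <- res$server
      begin_delay(sim, p, res$arrival - sim$clock, "consult_seize")
    },
    consult_seize = {
      cons <- p$consults[[p$consult_idx]]
      needs <- 1L; names(needs) <- p$consult_server
      # a resuscitation patient also holds the ED physician during the consult
      if (p$ctas == "I") needs <- c(needs, Physician = 1L)
      seize(sim, needs, ctas_num(p$ctas),
            list(kind = "consult", patient = p, duration = cons$duration))
    },
    consult_discuss = begin_task(sim, p, "discuss_specialist", "consult_done"),
    consult_done = {
      p$consult_idx <- p$consult_idx + 1L
      advance_patient(sim, p, "consult_start")
    },
    disposition = begin_task(sim, p, "make_disposition", "after_dispo",
                             duration = if (p$admit) 30 else 3),
    after_dispo = {
      p$disposition_time <- sim$clock
      if (p$admit) begin_task(sim, p, "determine_care_plan", "admission_form")
      else begin_task(sim, p, "care_plan_final", "instruction")
    },
    admission_form = begin_task(sim, p, "admission_form", "ssu_request"),
    ssu_request = {
      p$ssu_request <- sim$clock
      seize(sim, c(SSU = 1L), ctas_num(p$ctas),
            list(kind = "ssu_bed", patient = p))
    },
    ssu_arrive = {
      p$ssu_transfer <- sim$clock
      p$departure <- sim$clock
      p$outcome <- "admitted_ssu"
      stay <- ssu_stay_duration(sim$streams$routing, scn$ssu_stay_range)
      schedule_event(sim, sim$clock + stay, "ssu_free", NULL)
    },
    instruction = begin_task(sim, p, "give_instruction", "prep_patient"),
    prep_patient = begin_task(sim, p, "prepare_patient", "depart"),
    depart = {
      p$departure <- sim$clock
      p$outcome <- "discharged"
      schedule_event(sim, sim$clock, "free_bed",
                     list(area = p$area, team = p$team,
                          prio = ctas_num(p$ctas)))
    },
    stop("unreachable pathway stage: ", stage)
  )
}

engine_handlers <- function() list(
  arrival = function(sim, ev) {
    p <- ev$data
    advance_patient(sim, p, "start")
  },
  task_end = function(sim, ev) {
    d <- ev$data
    tag <- d$tag
    rel <- d$needs
    if (!is.null(tag$also_release)) rel <- c(rel, tag$also_release)
    p <- tag$patient
    if (!is.null(p)) {
      p$path_min <- p$path_min + d$dur
      if (tag$task %in% c("triage", "ehs_triage")) p$triage_end <- sim$clock
    }
    if (length(rel)) release(sim, rel)
    if (!is.null(p) && !is.null(tag$next_stage))
      advance_patient(sim, p, tag$next_stage)
  },
  delay_end = function(sim, ev) {
    d <- ev$data
    d$patient$path_min <- d$patient$path_min + d$dur
    advance_patient(sim, d$patient, d$next_stage)
  },
  free_bed = function(sim, ev) {
    # the nurse team turns the room over; the bed stays blocked meanwhile
    d <- ev$data
    seize(sim, stats::setNames(1L, d$team), d$prio,
          list(kind = "task", task = "prepare_room", patient = NULL,
               next_stage = NULL,
               also_release = stats::setNames(1L, d$area)))
  },
  global_end = function(sim, ev) release(sim, ev$data$needs),
  ssu_free = function(sim, ev) release(sim, c(SSU = 1L)),
  # staff briefings hold whoever is free when they start: staff mid-task
  # finish that task and skip the briefing (keeps the pools deadlock-free)
  huddle = function(sim, ev) {
    for (nm in STAFF_ROLES) {
      pool <- sim$pools[[nm]]
      n <- pool_capacity(pool, sim$clock) - pool$busy
      if (n > 0)
        seize(sim, stats::setNames(as.integer(n), nm), -1,
              list(kind = "global", duration = 10))
    }
  },
  shift_change = function(sim, ev) {
    pool <- sim$pools$Physician
    n <- pool_capacity(pool, sim$clock) - pool$busy
    if (n > 0)
      seize(sim, c(Physician = as.integer(n)), -1,
            list(kind = "global", duration = 5))
  }
)

new_patient <- function(sim, id, time, ctas) {
  scn <- sim$scn
  st <- sim$streams
  p <- new.env(parent = emptyenv())
  p$id <- id
  p$arrival <- time
  p$ctas <- ctas
  p$team <- nurse_team_for(ctas)
  p$category <- sample_category(st$attributes, 1L, scn$categories)
  p$mode <- assign_mode(st$attributes, scn$p_ems)
  p$exams <- assign_exams(ctas, p$category, st$exams, scn$exam_probs)
  p$exam_idx <- 1L
  p$consults <- needs_consult(ctas, p$category, st$consults,
                              scn$consults, scn$p_second_consult)
  p$consult_idx <- 1L
  p$admit <- stream_runif(st$routing) < scn$p_admit
  p$procedure <- scn$p_procedure > 0 &&
    stream_runif(st$routing) < scn$p_procedure
  p$area <- NA_character_
  p$triage_end <- NA_real_; p$bed_assigned <- NA_real_
  p$first_physician <- NA_real_; p$disposition_time <- NA_real_
  p$ssu_request <- NA_real_; p$ssu_transfer <- NA_real_
  p$departure <- NA_real_
  p$outcome <- "in_system"
  p$path_min <- 0
  p$consult_server <- NA_character_
  p
}

#' Run one replication
#'
#' Simulates one seeded replication of a scenario: pre-samples the arrival
#' process, drives every patient through the triage-to-departure pathway, and
#' returns the per-patient event log plus resource busy-time integrals.
#' Identical `(scenario, seed, replication)` triples give bit-identical logs.
#'
#' @param scenario an [ed_scenario()].
#' @param replication replication index (feeds the substream seeds).
#' @param seed master seed; defaults to the scenario's.
#' @return list with `patients` (data.frame, one row per arrived patient),
#'   `utilization` (data.frame of busy/scheduled minutes per pool over the
#'   collection window) and `window`.
#' @export
run_replication <- function(scenario, replication = 1L,
                            seed = scenario$seed) {
  stopifnot(inherits(scenario, "ed_scenario"))
  sim <- sim_core(scenario$horizon, window = c(scenario$warmup,
                                               scenario$horizon))
  sim$scn <- scenario
  sim$streams <- ed_streams(seed, replication)
  sim$on_grant <- engine_on_grant
  sim$handlers <- engine_handlers()

  for (role in STAFF_ROLES) {
    pool <- add_pool(sim, role, schedule = scenario$staffing[[role]])
    schedule_shift_events(sim, pool)
  }
  for (a in AREAS) add_pool(sim, a, capacity = scenario$locations[[a]])
  # specialists: capacity from the roster; availability windows are enforced
  # at call time (specialist_arrival_time), the pool holds consult seats
  for (i in seq_len(nrow(scenario$specialists)))
    add_pool(sim, scenario$specialists$name[i],
             capacity = scenario$specialists$count[i])

  arr <- sample_arrival_times(scenario$arrivals, scenario$scale,
                              scenario$horizon, sim$streams$arrivals)
  patients <- vector("list", nrow(arr))
  for (i in seq_len(nrow(arr))) {
    p <- new_patient(sim, i, arr$time[i], arr$ctas[i])
    patients[[i]] <- p
    schedule_event(sim, p$arrival, "arrival", p)
  }

  if (isTRUE(scenario$global_tasks)) {
    for (d in seq(0, scenario$horizon - 1, by = 1440))
      schedule_event(sim, d + 7 * 60, "huddle", NULL)
    ph <- scenario$staffing$Physician
    if (nrow(ph) > 0) {
      for (b in sort(unique(c(ph$start, ph$end))))
        for (d in seq(0, scenario$horizon - 1, by = 1440)) {
          t <- d + b
          if (t > 0 && t < scenario$horizon)
            schedule_event(sim, t, "shift_change", NULL)
        }
    }
  }

  run_loop(sim)

  log <- data.frame(
    patient_id = vapply(patients, function(p) p$id, 0L),
    replication = rep(as.integer(replication), length(patients)),
    arrival_min = vapply(patients, function(p) p$arrival, 0),
    ctas = vapply(patients, function(p) p$ctas, ""),
    category = vapply(patients, function(p) p$category, ""),
    mode = vapply(patients, function(p) p$mode, ""),
    area = vapply(patients, function(p) p$area, ""),
    triage_end = vapply(patients, function(p) p$triage_end, 0),
    bed_assigned = vapply(patients, function(p) p$bed_assigned, 0),
    first_physician = vapply(patients, function(p) p$first_physician, 0),
    disposition_time = vapply(patients, function(p) p$disposition_time, 0),
    ssu_request = vapply(patients, function(p) p$ssu_request, 0),
    ssu_transfer = vapply(patients, function(p) p$ssu_transfer, 0),
    departure = vapply(patients, function(p) p$departure, 0),
    path_min = vapply(patients, function(p) p$path_min, 0),
    outcome = vapply(patients, function(p) {
      if (p$outcome != "in_system") p$outcome
      else if (is.na(p$triage_end)) "untriaged" else "in_system"
    }, ""),
    stringsAsFactors = FALSE)

  w <- sim$window
  util <- do.call(rbind, lapply(c(STAFF_ROLES, AREAS), function(nm) {
    pool <- sim$pools[[nm]]
    sched <- if (!is.null(pool$capacity))
      pool$capacity * (w[2] - w[1])
    else scheduled_minutes(pool$schedule, w[1], w[2])
    cap <- if (!is.null(pool$capacity)) pool$capacity
           else if (nrow(pool$schedule)) max(vapply(
             seq(0, 1439, by = 30), function(tt)
               scheduled_headcount(pool$schedule, tt), 0L)) else 0L
    data.frame(pool = nm, busy_min = pool$busy_integral,
               scheduled_min = sched, max_busy = pool$max_busy,
               capacity = cap,
               utilization = if (sched > 0) pool$busy_integral / sched else NA,
               stringsAsFactors = FALSE)
  }))
  list(patients = log, utilization = util, window = w)
}

#' Simulate a scenario over replications
#'
#' Runs `replications` seeded replications and assembles the per-patient logs,
#' per-replication KPI reports and their across-replication summary.
#'
#' @param scenario an [ed_scenario()].
#' @param replications number of replications (default from the scenario).
#' @param seed master seed (default from the scenario).
#' @param keep_patients keep the combined per-patient log (can be large).
#' @return object of class `ed_sim` with elements `kpis` (list of per-rep
#'   [compute_kpis()] reports), `summary` ([aggregate_kpis()]), `utilization`,
#'   and optionally `patients`.
#' @export
ed_simulate <- function(scenario, replications = scenario$replications,
                        seed = scenario$seed, keep_patients = TRUE) {
  reps <- lapply(seq_len(replications), function(r)
    run_replication(scenario, r, seed))
  kpis <- lapply(reps, function(r)
    compute_kpis(r$patients, r$window))
  util <- do.call(rbind, lapply(seq_along(reps), function(i) {
    u <- reps[[i]]$utilization; u$replication <- i; u
  }))
  out <- list(scenario = scenario, replications = replications, seed = seed,
              kpis = kpis, summary = aggregate_kpis(kpis),
              utilization = util)
  if (keep_patients)
    out$patients <- do.call(rbind, lapply(reps, `[[`, "patients"))
  class(out) <- "ed_sim"
  out
}

#' @export
print.ed_sim <- function(x, ...) {
  cat("ED simulation:", x$replications, "replication(s), seed", x$seed, "\n\n")
  print(x$summary)
  invisible(x)
}
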