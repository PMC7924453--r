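# Scenario objects: the full parameterisation of one simulated ED — location
# capacities, shift-scheduled staffing, specialist roster, arrival source,
# distribution overrides, horizon/warm-up and replication control.

#' Build a shift schedule
#'
#' @param blocks named integer vector: names are `"HH:MM-HH:MM"` clock ranges
#'   (end before start wraps midnight), values headcounts.  Overlapping blocks
#'   add.  All blocks use the half-open `[start, end)` convention.
#' @return data.frame with `start`, `end` (minutes of day) and `count`.
#' @examples
#' shift_schedule(c("07:00-19:00" = 3, "19:00-07:00" = 3))
#' @export
shift_schedule <- function(blocks) {
  if (length(blocks) == 0)
    return(data.frame(start = numeric(0), end = numeric(0), count = integer(0)))
  parse_hm <- function(s) {
    p <- as.integer(strsplit(s, ":")[[1]])
    p[1] * 60 + p[2]
  }
  parts <- strsplit(names(blocks), "-")
  data.frame(
    start = vapply(parts, function(p) parse_hm(p[1]), 0),
    end = vapply(parts, function(p) parse_hm(p[2]), 0),
    count = as.integer(blocks))
}

#' Scheduled headcount at a time
#'
#' Sums the headcounts of all blocks containing clock time `t` (minutes since
#' the simulation origin), under the half-open `[start, end)` convention and
#' with midnight-wrapping blocks handled.
#'
#' @param schedule a [shift_schedule()].
#' @param t minutes since origin (Monday 00:00).
#' @return integer headcount.
#' @export
scheduled_headcount <- function(schedule, t) {
  if (nrow(schedule) == 0) return(0L)
  tod <- t %% 1440
  active <- ifelse(schedule$end > schedule$start,
                   tod >= schedule$start & tod < schedule$end,
                   tod >= schedule$start | tod < schedule$end)
  # end == start means a 24 h block
  active <- active | (schedule$end == schedule$start)
  as.integer(sum(schedule$count[active]))
}

# the four standard 12 h staff shifts
std_shifts <- function(counts) {
  stopifnot(length(counts) == 4)
  shift_schedule(c("07:00-19:00" = counts[1], "09:00-21:00" = counts[2],
                   "11:00-23:00" = counts[3], "19:00-07:00" = counts[4]))
}

#' Default staffing presets
#'
#' Per-shift headcounts for the two shipped scenarios.  The final-planning
#' staffing follows the published per-shift table (porters moved to the
#' standard shifts); the initial-planning totals (TN 3, EDN1 9, EDN2 8,
#' physicians 12, porters 3) are split across shifts using the published
#' low-level vectors where the totals match, an assumed `(4,2,2,4)` split for
#' physicians, and one porter on each of the historical porter shifts.
#'
#' @param preset `"IP"` or `"FP"`.
#' @return named list of [shift_schedule()]s, one per staff role.
#' @export
ed_staffing <- function(preset = c("IP", "FP")) {
  preset <- match.arg(preset)
  base <- list(Registration = shift_schedule(c("00:00-00:00" = 1)),
               Admin = shift_schedule(c("00:00-00:00" = 1)))
  if (preset == "IP") {
    c(list(
      TN = std_shifts(c(1, 0, 1, 1)),
      EDN1 = std_shifts(c(4, 0, 1, 4)),
      EDN2 = std_shifts(c(3, 1, 1, 3)),
      Physician = std_shifts(c(4, 2, 2, 4)),
      Porter = shift_schedule(c("07:00-19:00" = 1, "10:00-18:00" = 1,
                                "19:00-07:00" = 1))), base)
  } else {
    c(list(
      TN = std_shifts(c(1, 0, 1, 2)),
      EDN1 = std_shifts(c(4, 2, 0, 3)),
      EDN2 = std_shifts(c(3, 1, 2, 3)),
      Physician = std_shifts(c(3, 2, 2, 3)),
      Porter = std_shifts(c(3, 1, 0, 3))), base)
  }
}

#' Define a simulation scenario
#'
#' Collects every tunable of one simulated ED.  Defaults reproduce the
#' initial-planning configuration with the synthetic arrival profile; use
#' [scenario_ip()] / [scenario_fp()] for the two shipped presets.
#'
#' @param locations named capacities for `BA`, `MBA`, `VA`, `SSU`.
#' @param staffing named list of [shift_schedule()]s per staff role.
#' @param arrivals an [ed_rate_table()] (or an [ed_profile_spec()], which is
#'   expanded with [build_synthetic_table()]).
#' @param scale arrival-rate multiplier in (0, 1].
#' @param p_ems ambulance fraction (assumption, not a printed value).
#' @param p_admit short-stay-unit admission probability.
#' @param p_procedure probability of a bedside medical procedure.
#' @param p_second_consult probability of a second specialist consult.
#' @param specialists roster data.frame, see [ed_specialist_roster()].
#' @param tasks task table, see [ed_tasks()].
#' @param exam_probs exam probability array, see [ed_exam_probs()].
#' @param consults consult table, see [ed_consults()].
#' @param categories category mix, see [ed_categories()].
#' @param turnaround_lab,turnaround_imaging result turnaround distributions.
#' @param transport_leg DI transport-leg duration (each way).
#' @param ssu_stay_range short-stay-unit stay range in minutes.
#' @param global_tasks run the daily 07:00 huddle and physician shift-change
#'   briefings?
#' @param warmup,horizon minutes; statistics are collected on
#'   `[warmup, horizon)` with patients attributed by arrival time.
#' @param replications default replication count.
#' @param seed master seed.
#' @return object of class `ed_scenario`.
#' @export
ed_scenario <- function(locations = c(BA = 45, MBA = 3, VA = 10, SSU = 10),
                        staffing = ed_staffing("IP"),
                        arrivals = ed_profile_spec(),
                        scale = 1,
                        p_ems = 0.15,
                        p_admit = 0.2,
                        p_procedure = 0,
                        p_second_consult = 0,
                        specialists = ed_specialist_roster(fp = FALSE),
                        tasks = ed_tasks(),
                        exam_probs = ed_exam_probs(),
                        consults = ed_consults(),
                        categories = ed_categories(),
                        turnaround_lab = dist_tri(30, 45, 90),
                        turnaround_imaging = dist_tri(20, 30, 60),
                        transport_leg = dist_tri(0.5, 1, 2),
                        ssu_stay_range = c(1440, 4320),
                        global_tasks = TRUE,
                        warmup = 1440,
                        horizon = 11520,
                        replications = 30L,
                        seed = 1L) {
  if (inherits(arrivals, "ed_profile_spec"))
    arrivals <- build_synthetic_table(arrivals)
  stopifnot(inherits(arrivals, "ed_rate_table"),
            all(AREAS %in% names(locations)), all(locations >= 0),
            scale > 0, replications >= 1, warmup < horizon, warmup >= 0)
  miss <- setdiff(STAFF_ROLES, names(staffing))
  if (length(miss)) stop("staffing missing roles: ", paste(miss, collapse = ", "))
  structure(list(
    locations = locations, staffing = staffing, arrivals = arrivals,
    scale = scale, p_ems = p_ems, p_admit = p_admit,
    p_procedure = p_procedure, p_second_consult = p_second_consult,
    specialists = specialists, tasks = tasks, exam_probs = exam_probs,
    consults = consults, categories = categories,
    turnaround_lab = turnaround_lab, turnaround_imaging = turnaround_imaging,
    transport_leg = transport_leg, ssu_stay_range = ssu_stay_range,
    global_tasks = global_tasks, warmup = warmup, horizon = horizon,
    replications = as.integer(replications), seed = as.integer(seed)),
    class = "ed_scenario")
}

#' Initial-planning scenario preset
#'
#' Pre-expansion configuration: BA 45, MBA 3, VA 10, SSU 10; historical
#' staffing totals; off-site specialists.
#' @param ... overrides passed to [ed_scenario()].
#' @export
scenario_ip <- function(...) {
  args <- list(...)
  defaults <- list(locations = c(BA = 45, MBA = 3, VA = 10, SSU = 10),
                   staffing = ed_staffing("IP"),
                   specialists = ed_specialist_roster(fp = FALSE))
  do.call(ed_scenario, utils::modifyList(defaults, args))
}

#' Final-planning scenario preset
#'
#' Recommended configuration: BA 45, MBA 5, VA 15, SSU 30; per-shift staffing
#' from the published resource table; psychiatrist, neurologist and Crisis
#' Response on site.
#' @param ... overrides passed to [ed_scenario()].
#' @export
scenario_fp <- function(...) {
  args <- list(...)
  defaults <- list(locations = c(BA = 45, MBA = 5, VA = 15, SSU = 30),
                   staffing = ed_staffing("FP"),
                   specialists = ed_specialist_roster(fp = TRUE))
  do.call(ed_scenario, utils::modifyList(defaults, args))
}

#' @export
print.ed_scenario <- function(x, ...) {
  cat("ED scenario\n")
  cat("  locations:", paste(names(x$locations), x$locations, collapse = ", "),
      "\n")
  tot <- vapply(x$staffing, function(s) sum(s$count), 0)
  cat("  staff totals:", paste(names(tot), tot, collapse = ", "), "\n")
  cat("  weekly arrivals (expected):", round(sum(x$arrivals) * x$scale, 1),
      " scale:", x$scale, "\n")
  cat("  horizon:", x$horizon, "min, warm-up:", x$warmup,
      "min, replications:", x$replications, ", seed:", x$seed, "\n")
  invisible(x)
}

#' Read a scenario from a YAML/JSON config file
#'
#' Sections: `locations` (BA/MBA/VA/SSU), `staffing` (role -> list of
#' `{start, end, count}` clock blocks), `arrivals` (`csv: path` or
#' `synthetic: {weekly_total, ...}`), `specialists` (`preset: IP|FP`) and
#' `run` (`{warmup_min, horizon_min, replications, seed, scale}`), plus
#' optional scalar overrides `p_ems`, `p_admit`.
#'
#' @param path YAML file path.
#' @return an [ed_scenario()].
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$locations)) args$locations <- unlist(cfg$locations)
  if (!is.null(cfg$staffing)) {
    staffing <- ed_staffing("IP")
    for (role in names(cfg$staffing)) {
      blocks <- cfg$staffing[[role]]
      v <- vapply(blocks, function(b) as.integer(b$count), 0L)
      names(v) <- vapply(blocks, function(b) paste0(b$start, "-", b$end), "")
      staffing[[role]] <- shift_schedule(v)
    }
    args$staffing <- staffing
  }
  if (!is.null(cfg$arrivals)) {
    if (!is.null(cfg$arrivals$csv)) {
      args$arrivals <- read_rate_table(cfg$arrivals$csv)
    } else if (!is.null(cfg$arrivals$synthetic)) {
      args$arrivals <- do.call(ed_profile_spec, cfg$arrivals$synthetic)
    }
  }
  if (!is.null(cfg$specialists$preset))
    args$specialists <- ed_specialist_roster(fp = cfg$specialists$preset == "FP")
  run <- cfg$run
  if (!is.null(run)) {
    map <- c(warmup_min = "warmup", horizon_min = "horizon",
             replications = "replications", seed = "seed", scale = "scale")
    for (k in names(map)) if (!is.null(run[[k]])) args[[map[[k]]]] <- run[[k]]
  }
  for (k in c("p_ems", "p_admit"))
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  do.call(ed_scenario, args)
}
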