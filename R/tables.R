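# Packaged model parameters: the treatment-category mix, the in-ED task table
# (durations and staff requirements), per-category exam probabilities by acuity
# group, and specialist consult probabilities/durations.  All values ship as
# defaults on the scenario object and every one can be overridden there.

CTAS_LEVELS <- c("I", "II", "III", "IV", "V")
CTAS_GROUPS <- c("I-II", "III", "IV-V")
CATEGORIES <- c("GMI", "RE", "GA", "OR", "CA", "DE", "GE",
                "ENT", "MH", "NE", "ARV", "OP", "GY", "SM")
EXAMS <- c("CT", "ECHO", "EKG", "US", "XR", "BW", "SP")
DI_EXAMS <- c("CT", "ECHO", "EKG", "US", "XR")
STAFF_ROLES <- c("TN", "Registration", "EDN1", "EDN2",
                 "Physician", "Admin", "Porter")
AREAS <- c("BA", "MBA", "VA", "SSU")

ctas_group <- function(ctas) {
  switch(ctas, I = "I-II", II = "I-II", III = "III", IV = "IV-V", V = "IV-V",
         stop("unknown CTAS level: ", ctas))
}

#' Treatment-category mix
#'
#' The fourteen treatment categories with their printed shares (which sum to
#' 99.8% and are renormalised to 1) and the specialist each maps to.
#'
#' @return data.frame with columns `category`, `specialist`, `prop_printed`
#'   (as printed, percent) and `prop` (renormalised probability).
#' @export
ed_categories <- function() {
  d <- data.frame(
    category = CATEGORIES,
    specialist = c(NA, "Respiratory Therapist", "Gastroenterologist",
                   "Orthopedist", "Cardiologist", "Dermatologist",
                   "Urologist", "Otolaryngologist", "Crisis Response",
                   "Neurologist", NA, "Ophthalmologist", "Gynecologist",
                   "Crisis Response"),
    prop_printed = c(17.7, 14.6, 11.9, 10.3, 9.7, 8.3, 6.1,
                     4.9, 4.3, 4.2, 4.0, 1.8, 1.1, 0.9),
    stringsAsFactors = FALSE)
  d$prop <- d$prop_printed / sum(d$prop_printed)
  d
}

#' In-ED task table
#'
#' Durations (minutes) and jointly-required staff for every in-department
#' task.  Multi-role tasks require all listed roles simultaneously.  `EDN`
#' resolves at run time to the patient's nurse team (EDN1 for CTAS I-II,
#' EDN2 for III-V).
#'
#' @return named list of task specs, each `list(duration = ed_dist,
#'   staff = character())`.
#' @export
ed_tasks <- function() {
  t <- function(duration, staff) list(duration = duration, staff = staff)
  list(
    triage              = t(dist_tri(4, 7, 10), "TN"),
    escort_to_bed       = t(dist_tri(0.5, 1, 2), "EDN"),
    register_patient    = t(dist_const(3), "Registration"),
    nurse_assessment    = t(dist_ctas(c(I = 15, II = 15, III = 10,
                                        IV = 5, V = 5)), "EDN"),
    physician_assessment = t(dist_tri(7, 12, 15), "Physician"),
    write_orders        = t(dist_tri(2, 4, 5), "Physician"),
    initiate_di_lab     = t(dist_tri(2, 2.5, 3), "Admin"),
    prepare_for_di      = t(dist_const(3), "EDN"),
    receive_tests       = t(dist_const(1), c("EDN", "Admin")),
    review_tests_nurse  = t(dist_const(1), "EDN"),
    review_tests_physician = t(dist_const(2), "Physician"),
    take_specimen       = t(dist_tri(4, 6, 15), "EDN"),
    medical_procedure   = t(dist_tri(15, 20, 60), c("EDN", "Physician")),
    initiate_consult    = t(dist_const(2), "Admin"),
    arrange_consultant  = t(dist_const(2), "Admin"),
    discuss_specialist  = t(dist_const(3), "Physician"),
    make_disposition    = t(dist_mix(0.2, 30, 3), "Physician"),
    admission_form      = t(dist_const(2), "EDN"),
    determine_care_plan = t(dist_tri(7, 10, 12), "Physician"),
    contact_specialist  = t(dist_const(5), "Physician"),
    transport_to_ssu    = t(dist_tri(15, 20, 25), c("EDN", "Porter")),
    care_plan_final     = t(dist_tri(2, 4, 10), "Physician"),
    give_instruction    = t(dist_tri(2, 5, 12), "EDN"),
    prepare_patient     = t(dist_tri(1, 2, 4), "EDN"),
    shift_change        = t(dist_const(5), "Physician"),
    ehs_call            = t(dist_const(1), c("TN", "EDN")),
    ehs_triage          = t(dist_tri(4, 7, 10), c("TN", "EDN")),
    prepare_room        = t(dist_const(1), "EDN"),
    huddle              = t(dist_const(10), "ALL")
  )
}

#' Exam probabilities by acuity group and category
#'
#' Probability that a patient of a given category and CTAS group has each exam
#' ordered (checkmarks are 1, crosses 0).  ARV patients have no exams.
#'
#' @return numeric array `[exam, ctas group, category]` of probabilities.
#' @export
ed_exam_probs <- function() {
  p <- array(0, dim = c(length(EXAMS), length(CTAS_GROUPS), length(CATEGORIES)),
             dimnames = list(EXAMS, CTAS_GROUPS, CATEGORIES))
  set <- function(exam, group, vals) {
    # vals named by category; unnamed categories stay 0
    p[exam, group, names(vals)] <<- vals
  }
  set("CT", "I-II", c(GMI = .01, GA = 1, OR = .5, GE = 1, ENT = 1,
                      NE = 1, OP = .5))
  set("CT", "III",  c(GMI = .01, GA = .5, OR = .1, GE = .5))
  set("CT", "IV-V", c(GMI = .01))
  set("ECHO", "I-II", c(CA = .1))
  set("EKG", "I-II", c(RE = 1, OR = .75, CA = 1, DE = .25))
  set("EKG", "III",  c(OR = .75, CA = 1))
  set("EKG", "IV-V", c(CA = 1))
  set("US", "I-II", c(GMI = .01, GA = 1, GE = 1, GY = 1))
  set("US", "III",  c(GMI = .01, GA = .5, GE = .5, GY = 1))
  set("US", "IV-V", c(GMI = .01))
  set("XR", "I-II", c(GMI = .5, RE = 1, GA = 1, OR = 1, CA = 1, DE = .25,
                      GE = 1, ENT = 1, NE = 1, OP = .25))
  set("XR", "III",  c(GMI = .5, RE = 1, GA = .5, OR = 1, CA = .75,
                      GE = .5, ENT = .25))
  set("XR", "IV-V", c(GMI = .5, RE = .25, OR = .5, CA = .75, NE = .25))
  set("BW", "I-II", c(GMI = .5, RE = 1, GA = 1, OR = 1, CA = 1, DE = .75,
                      GE = 1, ENT = 1, MH = 1, NE = 1, OP = 1, GY = 1, SM = 1))
  set("BW", "III",  c(GMI = .5, RE = 1, GA = 1, OR = 1, CA = 1, DE = .25,
                      GE = 1, ENT = .25, MH = 1, NE = 1, GY = 1, SM = 1))
  set("BW", "IV-V", c(GMI = .5, CA = .25, MH = .5, NE = .1, GY = .5,
                      SM = .75))
  set("SP", "I-II", c(RE = 1, GA = .5, OR = .25, DE = .25, GE = 1,
                      ENT = .25, MH = 1, NE = 1, GY = 1, SM = 1))
  set("SP", "III",  c(RE = .75, GA = .5, OR = .1, DE = .25, GE = 1,
                      ENT = .5, MH = 1, NE = .5, GY = 1, SM = 1))
  set("SP", "IV-V", c(RE = .25, GE = 1, MH = .5, GY = .5, SM = .75))
  p
}

#' Specialist consult demand and durations
#'
#' For each treatment category: probability of a first consult and the consult
#' duration, by CTAS group.  GMI and ARV never consult.
#'
#' @return named list (by category) of
#'   `list(specialist, prob = c(group = p), duration = list(group = ed_dist))`.
#' @export
ed_consults <- function() {
  cs <- function(specialist, prob, duration) {
    names(prob) <- CTAS_GROUPS
    if (inherits(duration, "ed_dist")) duration <- list(duration, duration, duration)
    names(duration) <- CTAS_GROUPS
    list(specialist = specialist, prob = prob, duration = duration)
  }
  list(
    RE = cs("Respiratory Therapist", c(.75, .10, 0),
            list(dist_const(60), dist_const(15), dist_const(0))),
    GA = cs("Gastroenterologist", c(1, .25, 0), dist_tri(15, 22, 30)),
    OR = cs("Orthopedist", c(1, 1, .5),
            list(dist_const(10), dist_const(5), dist_const(3))),
    CA = cs("Cardiologist", c(1, .5, .1), dist_tri(30, 45, 60)),
    DE = cs("Dermatologist", c(.25, .1, 0), dist_tri(30, 45, 60)),
    GE = cs("Urologist", c(1, 1, 0), dist_tri(15, 22, 30)),
    ENT = cs("Otolaryngologist", c(1, .5, 0),
             list(dist_const(60), dist_const(20), dist_const(0))),
    MH = cs("Crisis Response", c(1, 1, 1), dist_tri(60, 75, 90)),
    NE = cs("Neurologist", c(1, 1, 0),
            list(dist_const(60), dist_const(60), dist_const(0))),
    OP = cs("Ophthalmologist", c(.1, .05, 0), dist_tri(30, 45, 60)),
    GY = cs("Gynecologist", c(1, 1, 0), dist_tri(15, 22, 30)),
    SM = cs("Crisis Response", c(1, 1, 1), dist_tri(60, 75, 90))
  )
}

#' CTAS service-level targets
#'
#' Maximum time-to-physician per acuity level (minutes) and the short-stay-unit
#' transfer target.
#' @return list with `physician_wait` (named vector) and `ssu_transfer`.
#' @export
ed_service_targets <- function() {
  list(physician_wait = c(I = 0, II = 15, III = 30, IV = 60, V = 120),
       ssu_transfer = 180)
}
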