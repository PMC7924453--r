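# Care-pathway routing rules: care-area assignment, nurse-team mapping,
# probabilistic exam assignment, DI escort requirements, disposition, and the
# short-stay-unit length of stay.

#' Care area for a patient
#'
#' CTAS I-III go to the bed area (BA); mental-health and substance-misuse
#' patients of those levels target the mental-health bed area (MBA) first,
#' overflowing to BA when the MBA is full; CTAS IV-V sit in the vertical
#' area (VA).
#'
#' @param ctas CTAS level (`"I"`..`"V"`).
#' @param category treatment-category code.
#' @param mba_full logical; is the MBA at capacity right now?
#' @return `"BA"`, `"MBA"` or `"VA"`.
#' @export
area_for <- function(ctas, category, mba_full = FALSE) {
  if (ctas %in% c("IV", "V")) return("VA")
  if (category %in% c("MH", "SM") && !mba_full) return("MBA")
  "BA"
}

#' Nurse team serving a CTAS level
#'
#' @param ctas CTAS level.
#' @return `"EDN1"` (CTAS I-II) or `"EDN2"` (III-V).
#' @export
nurse_team_for <- function(ctas) {
  if (ctas %in% c("I", "II")) "EDN1" else "EDN2"
}

#' Assign exams to a patient
#'
#' Independent Bernoulli draw per exam with the packaged probability for the
#' patient's (CTAS group, category).
#'
#' @param ctas,category patient profile.
#' @param stream uniform substream.
#' @param probs exam probability array, see [ed_exam_probs()].
#' @return character vector of exam codes (possibly empty), in table order.
#' @export
assign_exams <- function(ctas, category, stream, probs = ed_exam_probs()) {
  p <- probs[, ctas_group(ctas), category]
  u <- stream_runif(stream, length(p))
  EXAMS[u < p]
}

#' Escort staff for a diagnostic-imaging transport
#'
#' CTAS I patients are escorted by a nurse and a porter; everyone else needs
#' only the porter.  Lab samples are taken at the bedside and need no escort.
#'
#' @param ctas CTAS level.
#' @param exam exam code.
#' @return character vector of required roles (`"EDN"` resolves to the
#'   patient's nurse team), empty for lab samples.
#' @export
escort_requirement <- function(ctas, exam) {
  if (!exam %in% DI_EXAMS) return(character(0))
  if (ctas == "I") c("EDN", "Porter") else "Porter"
}

#' Disposition draw
#'
#' Bernoulli admission decision: with probability `p_admit` the patient is
#' admitted to the short-stay unit (30-minute disposition, admission paperwork
#' and transport), otherwise discharged (3-minute disposition, care plan,
#' instructions, preparation).
#'
#' @param stream uniform substream.
#' @param p_admit admission probability (default ties to the 20%/80%
#'   disposition-duration split).
#' @return `"admit"` or `"discharge"`.
#' @export
dispose <- function(stream, p_admit = 0.2) {
  stopifnot(p_admit >= 0, p_admit <= 1)
  if (stream_runif(stream) < p_admit) "admit" else "discharge"
}

#' Short-stay-unit length of stay
#'
#' Continuous uniform between one and three days.
#'
#' @param stream uniform substream.
#' @param range minutes, default `c(1440, 4320)`.
#' @return stay duration in minutes.
#' @export
ssu_stay_duration <- function(stream, range = c(1440, 4320)) {
  range[1] + stream_runif(stream) * (range[2] - range[1])
}
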