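# Construction of the four dependent variables: in-hospital death,
# escalation of care, 30-day readmission, and (log) length of stay.

default_vasopressors <- c("adrenaline", "dobutamine", "dopamine", "milrinone",
                          "noradrenaline", "phenylephrine", "vasopressin")

#' Escalation-of-care configuration
#'
#' Escalation is a composite marker of critical illness: an ICU stay, an
#' intermediate-care (IMCU) stay, mechanical ventilation, daytime BiPAP, or
#' receipt of a vasopressor. Daytime BiPAP defaults to the half-open window
#' 08:00-20:00 local time: BiPAP at night is commonly chronic therapy for
#' sleep-disordered breathing, while daytime BiPAP proxies impending
#' respiratory failure.
#'
#' @param include_imcu count IMCU stays as escalation (default `TRUE`).
#' @param daytime_start_hour,daytime_end_hour daytime window bounds (hours,
#'   `start <= hour < end` qualifies).
#' @param vasopressor_names lowercase drug names that count as vasopressors.
#' @return a list of class `escalation_config`.
#' @export
escalation_config <- function(include_imcu = TRUE,
                              daytime_start_hour = 8,
                              daytime_end_hour = 20,
                              vasopressor_names = default_vasopressors) {
  stopifnot(daytime_start_hour >= 0, daytime_start_hour < daytime_end_hour,
            daytime_end_hour <= 24, length(vasopressor_names) > 0)
  structure(list(include_imcu = isTRUE(include_imcu),
                 daytime_start_hour = daytime_start_hour,
                 daytime_end_hour = daytime_end_hour,
                 vasopressor_names = tolower(trimws(vasopressor_names))),
            class = "escalation_config")
}

#' Length of stay in days
#'
#' Discharge minus admission, in days with the fractional part retained. A
#' zero-length stay is an error because the downstream log transform is
#' undefined at zero.
#'
#' @param admit,discharge POSIXct vectors.
#' @return numeric vector of positive day counts.
#' @export
compute_los <- function(admit, discharge) {
  los <- as.numeric(difftime(discharge, admit, units = "days"))
  if (any(los <= 0))
    stop("length of stay must be positive; ", sum(los <= 0),
         " record(s) have discharge at or before admit")
  los
}

#' Natural-log transform of length of stay
#'
#' Length of stay is strongly right-skewed; modeling runs on the natural-log
#' scale, which brings it close to normal.
#'
#' @param los positive numeric vector of day counts.
#' @return `log(los)`.
#' @export
log_transform_los <- function(los) {
  if (any(los <= 0)) stop("length of stay must be positive for log transform")
  log(los)
}

#' Escalation of care per hospitalization
#'
#' @param cohort an `elix_cohort`.
#' @param cfg an [escalation_config()].
#' @return named logical vector (names = hospitalization ids): `TRUE` when
#'   the stay included an ICU (or, if configured, IMCU) ward stay, any
#'   mechanical-ventilation event, a BiPAP event inside the daytime window,
#'   or a vasopressor event whose drug is on the configured list.
#' @export
escalation_of_care <- function(cohort, cfg = escalation_config()) {
  ids <- cohort$hospitalizations$hospitalization_id
  esc <- stats::setNames(logical(length(ids)), ids)

  ws <- cohort$ward_stays
  wanted <- c("icu", if (cfg$include_imcu) "imcu")
  hit <- unique(ws$hospitalization_id[ws$ward_class %in% wanted])
  esc[hit[hit %in% ids]] <- TRUE

  ev <- cohort$treatment_events
  if (nrow(ev)) {
    hour <- as.integer(format(ev$timestamp, "%H"))
    qualifying <- ev$kind == "mechanical_ventilation" |
      (ev$kind == "bipap" &
         hour >= cfg$daytime_start_hour & hour < cfg$daytime_end_hour) |
      (ev$kind == "vasopressor" &
         !is.na(ev$drug_name) & ev$drug_name %in% cfg$vasopressor_names)
    hit <- unique(ev$hospitalization_id[qualifying])
    esc[hit[hit %in% ids]] <- TRUE
  }
  esc
}

#' 30-day readmission per hospitalization
#'
#' A hospitalization counts as readmitted when the same patient has another
#' admission whose calendar admit date is strictly after this discharge date
#' and at most `window` days later (boundary inclusive). Computed within the
#' dataset only: readmissions to other facilities are invisible, and no
#' censoring correction is applied for deaths or stays discharged close to
#' the end of the observation window.
#'
#' @param hospitalizations data frame with `hospitalization_id`,
#'   `patient_id`, `admit`, `discharge`.
#' @param window day count for the readmission window (default 30).
#' @return named logical vector keyed by hospitalization id.
#' @export
readmissions_30d <- function(hospitalizations, window = 30) {
  h <- hospitalizations
  ord <- order(h$patient_id, h$admit)
  h <- h[ord, , drop = FALSE]
  admit_date <- as.Date(h$admit, tz = "UTC")
  discharge_date <- as.Date(h$discharge, tz = "UTC")
  out <- stats::setNames(logical(nrow(h)), h$hospitalization_id)

  overlap <- FALSE
  idx_by_patient <- split(seq_len(nrow(h)), h$patient_id)
  for (idx in idx_by_patient) {
    k <- length(idx)
    if (k < 2) next
    if (any(h$admit[idx][-1] < h$discharge[idx][-k])) overlap <- TRUE
    for (j in seq_len(k - 1)) {
      gaps <- as.integer(admit_date[idx][(j + 1):k] - discharge_date[idx][j])
      out[idx[j]] <- any(gaps >= 1 & gaps <= window)
    }
  }
  if (overlap)
    warning("overlapping admissions found for at least one patient; ",
            "processed in admit order")
  out[hospitalizations$hospitalization_id]
}

#' Build the full outcome set for every hospitalization
#'
#' Death comes from the record's own flag; escalation and readmission are
#' derived from ward stays, treatment events and the patient's admission
#' history. Death and escalation are not mutually exclusive: a patient who
#' was escalated and then died counts in both.
#'
#' @param cohort an `elix_cohort`.
#' @param cfg an [escalation_config()].
#' @param readmission_window days, boundary inclusive (default 30).
#' @return data frame with columns `hospitalization_id`, `died`,
#'   `escalation`, `readmit_30d`, `los_days`, `log_los`.
#' @export
build_outcomes <- function(cohort, cfg = escalation_config(),
                           readmission_window = 30) {
  h <- cohort$hospitalizations
  los <- compute_los(h$admit, h$discharge)
  data.frame(
    hospitalization_id = h$hospitalization_id,
    died = h$died_in_hospital,
    escalation = unname(escalation_of_care(cohort, cfg)),
    readmit_30d = unname(readmissions_30d(h, readmission_window)),
    los_days = los,
    log_los = log_transform_los(los),
    stringsAsFactors = FALSE)
}
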