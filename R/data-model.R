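# Tabular interchange format for hospitalization-level records.
#
# Three rectangular tables keyed by hospitalization_id:
#   hospitalizations.csv - one row per admission; diagnosis codes serialized
#                          as a semicolon-separated sub-field
#   ward_stays.csv       - long format: ward_class, start, end
#   treatment_events.csv - long format: kind, timestamp, drug_name
# Timestamps are ISO-8601 (UTC); booleans are "true"/"false".

ward_classes <- c("im_ward", "icu", "imcu", "short_stay", "cardiology",
                  "geriatrics", "other")
event_kinds <- c("mechanical_ventilation", "bipap", "vasopressor")
admission_sources <- c("emergency", "elective", "internal_transfer")
sexes <- c("male", "female")

parse_iso8601 <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  miss <- is.na(out) & !is.na(x) & nzchar(x)
  if (any(miss)) {
    out[miss] <- as.POSIXct(x[miss], format = "%Y-%m-%d", tz = "UTC")
  }
  out
}

format_iso8601 <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

parse_bool <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "1", "t")] <- TRUE
  out[tolower(x) %in% c("false", "0", "f")] <- FALSE
  out
}

split_codes <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE),
         function(v) trimws(v[nzchar(trimws(v))]))
}

#' Read hospitalization records from the delimited interchange format
#'
#' Parses the three-table extract (hospitalizations, ward stays, treatment
#' events). Rows that fail to parse or violate a record invariant (discharge
#' before admission, stays or events outside the admission interval, bad
#' enums) are rejected individually: the surviving records are returned and
#' the rejected rows are reported, with line numbers, in the `errors`
#' attribute and a message. A missing required column is a hard error.
#'
#' @param hospitalizations_file path to the per-admission table.
#' @param ward_stays_file,treatment_events_file optional companion tables.
#' @return An object of class `elix_cohort`: a list with data frames
#'   `hospitalizations` (with `diagnosis_codes` as a list column of character
#'   vectors), `ward_stays` and `treatment_events`, plus an `errors`
#'   attribute (data frame of file, line, message).
#' @export
read_hospitalizations <- function(hospitalizations_file,
                                  ward_stays_file = NULL,
                                  treatment_events_file = NULL) {
  errors <- list()
  note <- function(file, line, message) {
    errors[[length(errors) + 1L]] <<- data.frame(
      file = file, line = line, message = message, stringsAsFactors = FALSE)
  }

  raw <- utils::read.csv(hospitalizations_file, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("hospitalization_id", "patient_id", "admit", "discharge",
                "age_years", "sex", "admission_source", "died_in_hospital",
                "diagnosis_codes")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("missing required column(s) in ", hospitalizations_file, ": ",
         paste(missing_cols, collapse = ", "))
  if (!"drg" %in% names(raw)) raw$drg <- NA_character_

  hosp <- data.frame(
    hospitalization_id = raw$hospitalization_id,
    patient_id = raw$patient_id,
    admit = parse_iso8601(raw$admit),
    discharge = parse_iso8601(raw$discharge),
    age_years = suppressWarnings(as.numeric(raw$age_years)),
    sex = raw$sex,
    admission_source = raw$admission_source,
    died_in_hospital = parse_bool(raw$died_in_hospital),
    drg = suppressWarnings(as.integer(raw$drg)),
    stringsAsFactors = FALSE)
  hosp$diagnosis_codes <- split_codes(raw$diagnosis_codes)

  bad <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    for (i in which(cond)) note(hospitalizations_file, i + 1L, why)
    cond
  }
  drop <- bad(is.na(hosp$admit), "unparseable admit timestamp") |
    bad(is.na(hosp$discharge), "unparseable discharge timestamp") |
    bad(!is.na(hosp$admit) & !is.na(hosp$discharge) &
          hosp$discharge < hosp$admit,
        "invariant violated: discharge earlier than admit") |
    bad(is.na(hosp$age_years) | hosp$age_years < 0,
        "missing or negative age_years") |
    bad(!hosp$sex %in% sexes, "unknown sex") |
    bad(!hosp$admission_source %in% admission_sources,
        "unknown admission_source") |
    bad(is.na(hosp$died_in_hospital), "unparseable died_in_hospital")
  if (any(drop)) {
    message(sum(drop), " hospitalization row(s) rejected; see errors attribute")
    hosp <- hosp[!drop, , drop = FALSE]
    rownames(hosp) <- NULL
  }

  read_long <- function(file, cols, what) {
    if (is.null(file))
      return(stats::setNames(
        as.data.frame(replicate(length(cols), character(0), simplify = FALSE)),
        cols))
    tab <- utils::read.csv(file, stringsAsFactors = FALSE,
                           colClasses = "character")
    missing_cols <- setdiff(cols, names(tab))
    if (length(missing_cols))
      stop("missing required column(s) in ", file, ": ",
           paste(missing_cols, collapse = ", "))
    tab
  }

  ws_raw <- read_long(ward_stays_file,
                      c("hospitalization_id", "ward_class", "start", "end"))
  ward_stays <- data.frame(
    hospitalization_id = ws_raw$hospitalization_id,
    ward_class = ws_raw$ward_class,
    start = parse_iso8601(ws_raw$start),
    end = parse_iso8601(ws_raw$end),
    stringsAsFactors = FALSE)
  if (nrow(ward_stays)) {
    drop_ws <- is.na(ward_stays$start) | is.na(ward_stays$end) |
      ward_stays$end < ward_stays$start |
      !ward_stays$ward_class %in% ward_classes |
      !ward_stays$hospitalization_id %in% hosp$hospitalization_id
    for (i in which(drop_ws))
      note(ward_stays_file, i + 1L, "invalid or orphaned ward stay row")
    ward_stays <- ward_stays[!drop_ws, , drop = FALSE]
    rownames(ward_stays) <- NULL
  }

  ev_raw <- read_long(treatment_events_file,
                      c("hospitalization_id", "kind", "timestamp", "drug_name"))
  events <- data.frame(
    hospitalization_id = ev_raw$hospitalization_id,
    kind = ev_raw$kind,
    timestamp = parse_iso8601(ev_raw$timestamp),
    drug_name = ifelse(nzchar(trimws(ev_raw$drug_name)),
                       tolower(trimws(ev_raw$drug_name)), NA_character_),
    stringsAsFactors = FALSE)
  if (nrow(events)) {
    drop_ev <- is.na(events$timestamp) | !events$kind %in% event_kinds |
      (events$kind == "vasopressor") == is.na(events$drug_name) |
      !events$hospitalization_id %in% hosp$hospitalization_id
    for (i in which(drop_ev))
      note(treatment_events_file, i + 1L, "invalid or orphaned event row")
    events <- events[!drop_ev, , drop = FALSE]
    rownames(events) <- NULL
  }

  new_cohort(hosp, ward_stays, events,
             errors = do.call(rbind, c(errors, list(
               data.frame(file = character(0), line = integer(0),
                          message = character(0), stringsAsFactors = FALSE)))))
}

new_cohort <- function(hospitalizations, ward_stays, treatment_events,
                       errors = NULL) {
  structure(list(hospitalizations = hospitalizations,
                 ward_stays = ward_stays,
                 treatment_events = treatment_events),
            errors = errors, class = "elix_cohort")
}

#' @export
print.elix_cohort <- function(x, ...) {
  cat("<elix_cohort> ", nrow(x$hospitalizations), " hospitalizations, ",
      nrow(x$ward_stays), " ward stays, ",
      nrow(x$treatment_events), " treatment events\n", sep = "")
  invisible(x)
}

#' Write a cohort back to the delimited interchange format
#'
#' Inverse of [read_hospitalizations()]; a write-then-read round trip
#' reproduces every field of a valid cohort.
#'
#' @param cohort an `elix_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- cohort$hospitalizations
  out <- data.frame(
    hospitalization_id = h$hospitalization_id,
    patient_id = h$patient_id,
    admit = format_iso8601(h$admit),
    discharge = format_iso8601(h$discharge),
    age_years = h$age_years,
    sex = h$sex,
    admission_source = h$admission_source,
    died_in_hospital = ifelse(h$died_in_hospital, "true", "false"),
    diagnosis_codes = vapply(h$diagnosis_codes, paste, character(1),
                             collapse = ";"),
    drg = h$drg,
    stringsAsFactors = FALSE)
  paths <- file.path(dir, c("hospitalizations.csv", "ward_stays.csv",
                            "treatment_events.csv"))
  utils::write.csv(out, paths[1], row.names = FALSE, na = "")
  ws <- cohort$ward_stays
  ws$start <- format_iso8601(ws$start)
  ws$end <- format_iso8601(ws$end)
  utils::write.csv(ws, paths[2], row.names = FALSE, na = "")
  ev <- cohort$treatment_events
  ev$timestamp <- format_iso8601(ev$timestamp)
  utils::write.csv(ev, paths[3], row.names = FALSE, na = "")
  invisible(paths)
}

#' Validate a cohort against the record invariants
#'
#' Report-only: never modifies or drops records. Checks duplicate
#' hospitalization ids, discharge/admit ordering, containment of ward stays
#' and treatment events within their admission interval, vasopressor events
#' without a drug name, and per-field missingness.
#'
#' @param cohort an `elix_cohort`.
#' @return a list with `n`, `duplicate_ids`, `violations` (data frame of
#'   hospitalization_id and message) and `missingness` (named counts).
#' @export
validate_dataset <- function(cohort) {
  h <- cohort$hospitalizations
  violations <- list()
  add <- function(ids, message) {
    if (length(ids))
      violations[[length(violations) + 1L]] <<- data.frame(
        hospitalization_id = ids, message = message, stringsAsFactors = FALSE)
  }

  dup <- unique(h$hospitalization_id[duplicated(h$hospitalization_id)])
  add(dup, "duplicate hospitalization_id")
  add(h$hospitalization_id[h$discharge < h$admit], "discharge earlier than admit")

  idx <- match(cohort$ward_stays$hospitalization_id, h$hospitalization_id)
  ws_bad <- !is.na(idx) &
    (cohort$ward_stays$start < h$admit[idx] |
       cohort$ward_stays$end > h$discharge[idx] |
       cohort$ward_stays$end < cohort$ward_stays$start)
  add(unique(cohort$ward_stays$hospitalization_id[ws_bad]),
      "ward stay outside admission interval")
  add(unique(cohort$ward_stays$hospitalization_id[is.na(idx)]),
      "ward stay for unknown hospitalization")

  idx <- match(cohort$treatment_events$hospitalization_id, h$hospitalization_id)
  ev_bad <- !is.na(idx) &
    (cohort$treatment_events$timestamp < h$admit[idx] |
       cohort$treatment_events$timestamp > h$discharge[idx])
  add(unique(cohort$treatment_events$hospitalization_id[ev_bad]),
      "treatment event outside admission interval")
  add(unique(cohort$treatment_events$hospitalization_id[is.na(idx)]),
      "treatment event for unknown hospitalization")
  vp <- cohort$treatment_events$kind == "vasopressor"
  add(unique(cohort$treatment_events$hospitalization_id[
    (vp & is.na(cohort$treatment_events$drug_name)) |
      (!vp & !is.na(cohort$treatment_events$drug_name))]),
    "drug_name present exactly when kind is vasopressor violated")

  violations <- do.call(rbind, c(violations, list(
    data.frame(hospitalization_id = character(0), message = character(0),
               stringsAsFactors = FALSE))))
  missingness <- vapply(
    h[c("patient_id", "admit", "discharge", "age_years", "sex",
        "admission_source", "died_in_hospital", "drg")],
    function(col) sum(is.na(col)), integer(1))
  list(n = nrow(h),
       duplicate_ids = length(dup),
       violations = violations,
       missingness = missingness)
}
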