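#' @import Matrix
#' @importFrom stats rpois rexp rnorm runif aggregate predict
#' @importFrom utils adist
NULL

EVENT_TYPES <- c("TEXT_ENTITY", "ICD", "ATC", "PROC", "LAB")

EVENT_COLS <- c("patient_id", "event_type", "surface", "date", "entity_class",
                "negated", "section_heading", "test_id", "value",
                "ref_low", "ref_high")

#' Construct an EHR case-control cohort
#'
#' An `ehr_cohort` bundles a patient table (one row per patient: identifier,
#' case/control group, age, diagnosis date for cases) with an event table
#' (one row per timestamped clinical event).  Five event types are
#' supported: free-text clinical entities (`TEXT_ENTITY`, lemmatized
#' surface forms with negation status and note-section heading), diagnosis
#' codes (`ICD`), drug codes (`ATC`), procedure codes (`PROC`) and lab
#' results (`LAB`, with a numeric value and reference range).
#'
#' @param patients data frame with columns `patient_id`, `group`
#'   (`"case"`/`"control"`), `age` and `diagnosis_date` (`Date`; `NA` for
#'   controls).
#' @param events data frame with columns `patient_id`, `event_type`,
#'   `surface`, `date` and the optional per-type columns `entity_class`,
#'   `negated`, `section_heading`, `test_id`, `value`, `ref_low`,
#'   `ref_high`.
#' @return An object of class `ehr_cohort`.
#' @export
ehr_cohort <- function(patients, events) {
  stopifnot(is.data.frame(patients), is.data.frame(events))
  need_p <- c("patient_id", "group", "age", "diagnosis_date")
  if (!all(need_p %in% names(patients)))
    stop("patients must have columns: ", paste(need_p, collapse = ", "))
  for (col in setdiff(EVENT_COLS, names(events))) {
    fill <- switch(col,
      negated = NA,
      value = NA_real_, ref_low = NA_real_, ref_high = NA_real_,
      NA_character_)
    events[[col]] <- rep(fill, length.out = nrow(events))
  }
  events <- events[, EVENT_COLS]
  if (!all(patients$group %in% c("case", "control")))
    stop("group must be 'case' or 'control'")
  is_case <- patients$group == "case"
  if (any(is_case & is.na(patients$diagnosis_date)))
    stop("cases must have a diagnosis_date")
  if (any(!is_case & !is.na(patients$diagnosis_date)))
    stop("controls must not have a diagnosis_date")
  if (nrow(events)) {
    if (!all(events$event_type %in% EVENT_TYPES))
      stop("unknown event_type")
    if (any(is.na(events$surface) | !nzchar(events$surface)))
      stop("event surfaces must be non-empty")
    lab <- events$event_type == "LAB"
    lab_fields <- !is.na(events$test_id) & !is.na(events$value) &
      !is.na(events$ref_low) & !is.na(events$ref_high)
    if (any(lab & !lab_fields & !is.na(events$test_id)) &&
        !all(lab_fields[lab & !is.na(events$test_id)])) {
      # partially-present lab fields are rejected; fully absent bounds are
      # tolerated here and skipped (with a warning) at encoding time
      partial <- lab & !is.na(events$test_id) &
        (is.na(events$value) | xor(is.na(events$ref_low), is.na(events$ref_high)))
      if (any(partial)) stop("lab fields must be jointly present or absent")
    }
    if (!all(events$patient_id %in% patients$patient_id))
      stop("events refer to unknown patient_id")
  }
  structure(list(patients = patients, events = events), class = "ehr_cohort")
}

#' @exportS3Method print ehr_cohort
print.ehr_cohort <- function(x, ...) {
  n_case <- sum(x$patients$group == "case")
  n_ctrl <- sum(x$patients$group == "control")
  cat(sprintf("<ehr_cohort> %d cases, %d controls, %d events\n",
              n_case, n_ctrl, nrow(x$events)))
  if (nrow(x$events)) {
    tab <- table(x$events$event_type)
    cat("  events by type:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort an [ehr_cohort()].
#' @return Integer count of patients.
#' @export
n_patients <- function(cohort) nrow(cohort$patients)

# Keep only the events (and patient rows) named; internal helper.
subset_patients <- function(cohort, keep_ids) {
  ehr_cohort(cohort$patients[cohort$patients$patient_id %in% keep_ids, ,
                             drop = FALSE],
             cohort$events[cohort$events$patient_id %in% keep_ids, ,
                           drop = FALSE])
}

replace_events <- function(cohort, events) {
  cohort$events <- events
  cohort
}

#' Read and write cohorts as JSON Lines
#'
#' The on-disk dialect stores one event per line as a JSON object carrying
#' both the patient fields (`patient_id`, `group`, `age`, `diagnosis_date`)
#' and the event fields; dates are ISO-8601 strings.  Patients without any
#' events are written as a line with the patient fields only.
#'
#' @param cohort an [ehr_cohort()].
#' @param path file path.
#' @return `write_cohort_jsonl()` returns `path` invisibly;
#'   `read_cohort_jsonl()` returns an [ehr_cohort()].
#' @export
write_cohort_jsonl <- function(cohort, path) {
  pat <- cohort$patients
  ev <- cohort$events
  df <- merge(ev, pat, by = "patient_id", sort = FALSE)
  no_ev <- pat[!pat$patient_id %in% ev$patient_id, , drop = FALSE]
  if (nrow(no_ev)) {
    for (col in setdiff(names(df), names(no_ev))) no_ev[[col]] <- NA
    df <- rbind(df, no_ev[, names(df)])
  }
  ord <- order(df$patient_id, df$date, df$event_type, df$surface,
               method = "radix")
  df <- df[ord, c("patient_id", "group", "age", "diagnosis_date",
                  EVENT_COLS[-1])]
  df$date <- format(df$date)
  df$diagnosis_date <- format(df$diagnosis_date)
  con <- file(path, open = "wb")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE, na = "null", digits = NA)
  invisible(path)
}

#' @rdname write_cohort_jsonl
#' @export
read_cohort_jsonl <- function(path) {
  df <- jsonlite::stream_in(file(path), verbose = FALSE)
  for (col in c(EVENT_COLS[-1], "group", "age", "diagnosis_date"))
    if (is.null(df[[col]])) df[[col]] <- NA
  pat <- unique(df[, c("patient_id", "group", "age", "diagnosis_date")])
  pat$diagnosis_date <- as.Date(pat$diagnosis_date)
  ev <- df[!is.na(df$event_type), c("patient_id", EVENT_COLS[-1]),
           drop = FALSE]
  ev$date <- as.Date(ev$date)
  ev$negated <- as.logical(ev$negated)
  for (col in c("value", "ref_low", "ref_high"))
    ev[[col]] <- as.numeric(ev[[col]])
  ehr_cohort(pat, ev)
}
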