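#' Default grid of censoring cutoffs
#'
#' Prediction horizons in days before diagnosis: all data up to the day
#' before diagnosis (cutoff 1), then 14 days and every 30 days thereafter,
#' capped at one year.
#'
#' @return Integer vector of cutoffs (days).
#' @export
default_censor_grid <- function() {
  c(1L, seq(14L, 344L, by = 30L), 365L)
}

#' Select the analysis cohort
#'
#' Applies the inclusion and exclusion rules of a matched case-control
#' extraction: patients carrying the exclusion code (e.g. a
#' previous-disease history code) are removed entirely; cases must have at
#' least one event strictly before their diagnosis date; a case without a
#' recorded diagnosis date receives the date of its first diagnosis code
#' matching `case_code_prefix`; controls carrying any diagnosis code with
#' that prefix are removed.
#'
#' @param cohort an [ehr_cohort()].
#' @param case_code_prefix ICD prefix defining the case condition
#'   (default `"C53"`).
#' @param exclusion_code exact ICD code whose carriers are excluded
#'   (default `"Z854C"`).
#' @return The filtered [ehr_cohort()].
#' @export
select_cohort <- function(cohort, case_code_prefix = "C53",
                          exclusion_code = "Z854C") {
  pat <- cohort$patients
  ev <- cohort$events
  if (nrow(pat) == 0) return(cohort)
  icd <- ev[ev$event_type == "ICD", , drop = FALSE]
  excl <- unique(icd$patient_id[icd$surface == exclusion_code])
  pat <- pat[!pat$patient_id %in% excl, , drop = FALSE]
  ev <- ev[!ev$patient_id %in% excl, , drop = FALSE]
  icd <- icd[!icd$patient_id %in% excl, , drop = FALSE]

  hit <- icd[startsWith(icd$surface, case_code_prefix), , drop = FALSE]
  # date a case's diagnosis from its first matching code when unset
  undated <- pat$patient_id[pat$group == "case" & is.na(pat$diagnosis_date)]
  if (length(undated)) {
    h <- hit[hit$patient_id %in% undated, , drop = FALSE]
    if (nrow(h)) {
      first <- aggregate(date ~ patient_id, data = h, FUN = min)
      m <- match(pat$patient_id, first$patient_id)
      set <- !is.na(m) & pat$group == "case"
      pat$diagnosis_date[set] <- first$date[m[set]]
    }
  }
  # controls holding the case-defining code are not valid controls
  bad_ctrl <- intersect(unique(hit$patient_id),
                        pat$patient_id[pat$group == "control"])
  # cases need history: at least one event strictly before diagnosis,
  # and a diagnosis date at all
  diag <- pat$diagnosis_date[match(ev$patient_id, pat$patient_id)]
  pre <- !is.na(diag) & ev$date < diag
  with_hist <- unique(ev$patient_id[pre])
  bad_case <- pat$patient_id[pat$group == "case" &
                             (is.na(pat$diagnosis_date) |
                              !pat$patient_id %in% with_hist)]
  keep <- setdiff(pat$patient_id, c(bad_ctrl, bad_case))
  ehr_cohort(pat[pat$patient_id %in% keep, , drop = FALSE],
             ev[ev$patient_id %in% keep, , drop = FALSE])
}

#' Censor case events at a prediction horizon
#'
#' For cases, keeps exactly the events registered at least `cutoff_days`
#' days before the diagnosis date (the boundary is inclusive: an event
#' dated exactly `cutoff_days` before diagnosis is retained).  Control
#' streams are never truncated.
#'
#' @param cohort an [ehr_cohort()].
#' @param cutoff_days positive integer horizon in days.
#' @return The censored [ehr_cohort()].
#' @export
censor_events <- function(cohort, cutoff_days) {
  stopifnot(length(cutoff_days) == 1, cutoff_days >= 1)
  ev <- cohort$events
  diag <- cohort$patients$diagnosis_date[
    match(ev$patient_id, cohort$patients$patient_id)]
  keep <- is.na(diag) | as.integer(diag - ev$date) >= cutoff_days
  replace_events(cohort, ev[keep, , drop = FALSE])
}

#' Negation and family-note policies for textual events
#'
#' Negated text entities are either dropped (`negation_policy =
#' "exclude"`) or kept as distinct features by prefixing their surface
#' with the reserved marker `"NEG::"` (`"separate"`).  Text events filed
#' under note headings about family members are dropped when
#' `family_exclusion` is `TRUE`, removing mentions that describe relatives
#' rather than the patient.  Findings and disorders share one feature
#' namespace throughout (the entity class is metadata, never part of the
#' feature identity).
#'
#' @param cohort an [ehr_cohort()].
#' @param negation_policy `"exclude"` (default) or `"separate"`.
#' @param family_exclusion drop family-heading notes? Default `TRUE`.
#' @param family_headings character vector of section headings treated as
#'   family-related.
#' @return The transformed [ehr_cohort()].
#' @export
apply_text_policies <- function(cohort,
                                negation_policy = c("exclude", "separate"),
                                family_exclusion = TRUE,
                                family_headings = FAMILY_HEADINGS) {
  negation_policy <- match.arg(negation_policy)
  ev <- cohort$events
  is_txt <- ev$event_type == "TEXT_ENTITY"
  if (family_exclusion) {
    drop <- is_txt & !is.na(ev$section_heading) &
      ev$section_heading %in% family_headings
    ev <- ev[!drop, , drop = FALSE]
    is_txt <- ev$event_type == "TEXT_ENTITY"
  }
  neg <- is_txt & !is.na(ev$negated) & ev$negated
  if (negation_policy == "exclude") {
    ev <- ev[!neg, , drop = FALSE]
  } else {
    ev$surface[neg] <- paste0(NEG_MARKER, ev$surface[neg])
  }
  replace_events(cohort, ev)
}

NEG_MARKER <- "NEG::"

#' Remove events supported by a single patient
#'
#' An event surface (within its event type) that occurs for only one
#' patient cannot contribute to case-control discrimination; such
#' surfaces are removed everywhere, however many times that one patient
#' recorded them.
#'
#' @param cohort an [ehr_cohort()].
#' @return A list with elements `cohort` (pruned) and `removed` (data
#'   frame of `event_type`, `surface` pairs that were dropped).
#' @export
remove_rare_events <- function(cohort) {
  ev <- cohort$events
  if (nrow(ev) == 0)
    return(list(cohort = cohort,
                removed = data.frame(event_type = character(0),
                                     surface = character(0))))
  key <- paste(ev$event_type, ev$surface, sep = "\r")
  support <- rowsum(as.integer(!duplicated(paste(key, ev$patient_id, sep = "\r"))),
                    key)
  rare <- rownames(support)[support[, 1] == 1]
  drop <- key %in% rare
  removed <- unique(ev[drop, c("event_type", "surface")])
  rownames(removed) <- NULL
  list(cohort = replace_events(cohort, ev[!drop, , drop = FALSE]),
       removed = removed)
}

#' Permute case/control labels for null calibration
#'
#' Randomly reassigns the case/control labels across patients (keeping
#' the group sizes), severing any association between event streams and
#' the outcome.  Patients relabelled as cases receive a pseudo diagnosis
#' date one day after their last event, so that censoring keeps their
#' whole stream; relabelled controls lose their diagnosis date.  Running
#' the pipeline on a permuted cohort calibrates its null behaviour (AUC
#' should be close to 0.5).
#'
#' @param cohort an [ehr_cohort()].
#' @param seed integer seed.
#' @return The relabelled [ehr_cohort()].
#' @export
permute_labels <- function(cohort, seed = 1L) {
  pat <- cohort$patients
  pat$group <- with_seed(seed, sample(pat$group))
  pat$diagnosis_date <- as.Date(NA)
  is_case <- pat$group == "case"
  if (any(is_case) && nrow(cohort$events)) {
    last <- aggregate(date ~ patient_id, data = cohort$events, FUN = max)
    m <- match(pat$patient_id, last$patient_id)
    pat$diagnosis_date[is_case] <- last$date[m[is_case]] + 1
  }
  ehr_cohort(pat, cohort$events)
}

#' Split a cohort into development and test partitions
#'
#' Patient-level split, stratified by group so that the case:control ratio
#' is preserved within rounding, and deterministic under `seed`.
#'
#' @param cohort an [ehr_cohort()].
#' @param dev_fraction fraction of patients assigned to the development
#'   partition, in (0, 1); default 0.2.
#' @param seed integer seed.
#' @return A list with `dev` and `test` cohorts.
#' @export
split_dev_test <- function(cohort, dev_fraction = 0.2, seed = 1L) {
  stopifnot(dev_fraction > 0, dev_fraction < 1)
  pat <- cohort$patients
  dev_ids <- with_seed(seed, {
    unlist(lapply(split(pat$patient_id, pat$group), function(ids) {
      n_dev <- round(length(ids) * dev_fraction)
      sample(ids, n_dev)
    }), use.names = FALSE)
  })
  list(dev = subset_patients(cohort, dev_ids),
       test = subset_patients(cohort, setdiff(pat$patient_id, dev_ids)))
}
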