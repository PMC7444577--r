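# Small hand-built cohorts for unit tests; everything is constructed in
# code so the suite ships no data files.

mk_patients <- function(ids, groups, diag = NULL, age = 50) {
  data.frame(patient_id = ids, group = groups, age = age,
             diagnosis_date = if (is.null(diag)) as.Date(NA) else
               as.Date(diag),
             stringsAsFactors = FALSE)
}

mk_event <- function(pid, type, surface, date, entity_class = NA,
                     negated = NA, heading = NA, test_id = NA, value = NA,
                     ref_low = NA, ref_high = NA) {
  data.frame(patient_id = pid, event_type = type, surface = surface,
             date = as.Date(date), entity_class = entity_class,
             negated = negated, section_heading = heading,
             test_id = test_id, value = value, ref_low = ref_low,
             ref_high = ref_high, stringsAsFactors = FALSE)
}

# A tiny two-patient cohort with one case and one control.
tiny_cohort <- function() {
  pat <- mk_patients(c("p1", "p2"), c("case", "control"),
                     diag = c("2014-06-01", NA))
  ev <- rbind(
    mk_event("p1", "TEXT_ENTITY", "hosta", "2014-01-01",
             entity_class = "FINDING", negated = FALSE),
    mk_event("p1", "ICD", "C530", "2014-05-01"),
    mk_event("p2", "TEXT_ENTITY", "hosta", "2014-03-01",
             entity_class = "FINDING", negated = FALSE),
    mk_event("p2", "ATC", "N02BE01", "2014-07-01"))
  ehr_cohort(pat, ev)
}

# A generated cohort small enough for fast tests, cached per session.
small_gen <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(ehr_config(n_cases = 30,
                                           background_vocab_size = 800,
                                           seed = 11))
    cache
  }
})

signal_feature_ids <- function(gt) {
  s <- gt$signal_events
  ifelse(s$event_type == "TEXT_ENTITY",
         paste0("TEXT:L",
                pmin(lengths(strsplit(s$surface, " ", fixed = TRUE)), 4),
                ":", s$surface),
         ifelse(s$event_type == "ICD", paste0("ICD:full:", s$surface),
                ifelse(s$event_type == "ATC", paste0("ATC:full:", s$surface),
                       paste0("PROC:full:", s$surface))))
}

# Patients carrying a given signal surface at least once, counting
# injected spelling variants as the surface they stand for.
carriers <- function(cohort, gt, surface) {
  ev <- cohort$events
  vm <- gt$variant_map
  s <- ev$surface
  m <- match(s, vm$variant)
  s[!is.na(m)] <- vm$canonical[m[!is.na(m)]]
  unique(ev$patient_id[s == surface])
}
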