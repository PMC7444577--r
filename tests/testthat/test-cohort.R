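test_that("cohort selection applies exclusion and history rules", {
  pat <- mk_patients(c("a", "b", "c", "d", "e"),
                     c("case", "case", "control", "control", "case"),
                     diag = c("2014-06-01", "2014-06-01", NA, NA, NA))
  ev <- rbind(
    mk_event("a", "ICD", "C530", "2014-06-01"),      # only at/after diagnosis
    mk_event("b", "TEXT_ENTITY", "hosta", "2014-01-01"),
    mk_event("b", "ICD", "Z854C", "2014-02-01"),     # excluded outright
    mk_event("c", "ICD", "C539", "2013-01-01"),      # control with case code
    mk_event("d", "ATC", "N02BE01", "2013-01-01"),
    mk_event("e", "TEXT_ENTITY", "hosta", "2013-01-01"),
    mk_event("e", "ICD", "C530", "2013-06-01"))      # dates the diagnosis
  ev$patient_id <- as.character(ev$patient_id)
  # case e has no diagnosis_date: constructor forbids it, so build via
  # select_cohort from a raw frame
  pat$diagnosis_date[pat$patient_id == "e"] <- as.Date("2099-01-01")
  co <- ehr_cohort(pat, ev)
  co$patients$diagnosis_date[co$patients$patient_id == "e"] <- NA
  out <- select_cohort(co)
  ids <- out$patients$patient_id
  expect_false("a" %in% ids)  # no events strictly before diagnosis
  expect_false("b" %in% ids)  # exclusion code
  expect_false("c" %in% ids)  # control carrying the case code
  expect_true(all(c("d", "e") %in% ids))
  # e's diagnosis date comes from its first C53 code
  expect_equal(out$patients$diagnosis_date[out$patients$patient_id == "e"],
               as.Date("2013-06-01"))
  # empty input passes through
  empty <- subset_empty <- select_cohort(ehr_cohort(pat[0, ], ev[0, ]))
  expect_equal(n_patients(empty), 0)
})

test_that("censoring keeps the inclusive boundary and never touches controls", {
  pat <- mk_patients(c("k", "m"), c("case", "control"),
                     diag = c("2014-01-31", NA))
  ev <- rbind(
    mk_event("k", "TEXT_ENTITY", "x", "2014-01-17"),  # 14 days before
    mk_event("k", "TEXT_ENTITY", "y", "2014-01-20"),  # 11 days before
    mk_event("m", "TEXT_ENTITY", "x", "2014-06-01"),
    mk_event("m", "TEXT_ENTITY", "y", "2014-07-01"))
  co <- ehr_cohort(pat, ev)
  out <- censor_events(co, 14)
  kept <- out$events
  expect_equal(kept$surface[kept$patient_id == "k"], "x")  # boundary kept
  expect_equal(sort(kept$surface[kept$patient_id == "m"]), c("x", "y"))
  expect_error(censor_events(co, 0))
})

test_that("censoring is monotone: larger cutoffs never add events", {
  co <- select_cohort(small_gen()$cohort)
  grid <- default_censor_grid()
  expect_equal(grid[1:3], c(1L, 14L, 44L))
  expect_equal(grid[length(grid)], 365L)
  prev <- censor_events(co, grid[1])
  for (cut in grid[-1]) {
    cur <- censor_events(co, cut)
    expect_lte(nrow(cur$events), nrow(prev$events))
    # nesting at the event level for cases
    key <- function(x) paste(x$patient_id, x$event_type, x$surface, x$date)
    expect_true(all(key(cur$events) %in% key(prev$events)))
    prev <- cur
  }
})

test_that("negation and family policies transform text events as configured", {
  pat <- mk_patients("p", "control")
  ev <- rbind(
    mk_event("p", "TEXT_ENTITY", "hosta", "2014-01-01",
             entity_class = "FINDING", negated = TRUE),
    mk_event("p", "TEXT_ENTITY", "feber", "2014-01-02",
             entity_class = "FINDING", negated = FALSE),
    mk_event("p", "TEXT_ENTITY", "cancer", "2014-01-03",
             entity_class = "DISORDER", negated = FALSE,
             heading = "Hereditet"),
    mk_event("p", "ICD", "C530", "2014-01-04"))
  co <- ehr_cohort(pat, ev)
  excl <- apply_text_policies(co, "exclude")
  expect_false("hosta" %in% excl$events$surface)
  expect_false("cancer" %in% excl$events$surface)  # family note dropped
  expect_true(all(c("feber", "C530") %in% excl$events$surface))
  sep <- apply_text_policies(co, "separate")
  expect_true("NEG::hosta" %in% sep$events$surface)
  expect_false("hosta" %in% sep$events$surface)
  keep_family <- apply_text_policies(co, "separate", family_exclusion = FALSE)
  expect_true("cancer" %in% keep_family$events$surface)
  # no negated events: identity under either policy
  co2 <- ehr_cohort(pat, ev[ev$negated %in% c(FALSE, NA) &
                              is.na(ev$section_heading), ])
  expect_equal(apply_text_policies(co2, "exclude")$events,
               apply_text_policies(co2, "separate")$events)
})

test_that("rare-event removal uses patient-level support", {
  pat <- mk_patients(c("p", "q", "r"), rep("control", 3))
  ev <- rbind(
    mk_event(rep("p", 5), "PROC", "AA111", "2014-01-01"),  # 5x, one patient
    mk_event("p", "PROC", "BB222", "2014-01-02"),
    mk_event("q", "PROC", "BB222", "2014-01-03"),          # 2 patients
    mk_event("r", "TEXT_ENTITY", "BB222", "2014-01-04"))   # other type: alone
  co <- ehr_cohort(pat, ev)
  out <- remove_rare_events(co)
  expect_false("AA111" %in% out$cohort$events$surface)
  expect_true("BB222" %in%
                out$cohort$events$surface[out$cohort$events$event_type == "PROC"])
  # support is counted within event type: the text BB222 goes
  expect_false(any(out$cohort$events$event_type == "TEXT_ENTITY"))
  expect_setequal(paste(out$removed$event_type, out$removed$surface),
                  c("PROC AA111", "TEXT_ENTITY BB222"))
})

test_that("every retained surface has support >= 2 and the removed set is complementary", {
  co <- select_cohort(small_gen()$cohort)
  before <- unique(co$events[, c("event_type", "surface")])
  out <- remove_rare_events(co)
  ev <- out$cohort$events
  support <- tapply(ev$patient_id, paste(ev$event_type, ev$surface),
                    function(x) length(unique(x)))
  expect_true(all(support >= 2))  # brute-force recount
  after <- unique(ev[, c("event_type", "surface")])
  expect_equal(nrow(after) + nrow(out$removed), nrow(before))
  expect_length(intersect(paste(after$event_type, after$surface),
                          paste(out$removed$event_type, out$removed$surface)),
                0)
})

subset_two <- function(co) {
  ids <- co$patients$patient_id[co$patients$group == "control"][1:2]
  ehr_cohort(co$patients[co$patients$patient_id %in% ids, ],
             co$events[co$events$patient_id %in% ids, ])
}

test_that("dev/test split is stratified, exhaustive and deterministic", {
  gen <- small_gen()
  co <- gen$cohort
  sp <- split_dev_test(co, 0.2, seed = 4)
  dev_groups <- table(sp$dev$patients$group)
  expect_equal(unname(dev_groups["case"]), 6)      # 20% of 30
  expect_equal(unname(dev_groups["control"]), 60)  # 20% of 300
  ids_dev <- sp$dev$patients$patient_id
  ids_test <- sp$test$patients$patient_id
  expect_length(intersect(ids_dev, ids_test), 0)
  expect_setequal(c(ids_dev, ids_test), co$patients$patient_id)
  sp2 <- split_dev_test(co, 0.2, seed = 4)
  expect_identical(sort(sp2$dev$patients$patient_id), sort(ids_dev))
  # two patients at one half each
  two <- subset_two(co)
  sp3 <- split_dev_test(two, 0.5, seed = 1)
  expect_equal(n_patients(sp3$dev), 1)
  expect_equal(n_patients(sp3$test), 1)
  expect_error(split_dev_test(co, 0))
})

test_that("permuted labels keep group sizes and the diagnosis-date invariant", {
  co <- select_cohort(small_gen()$cohort)
  pm <- permute_labels(co, seed = 3)
  expect_equal(table(pm$patients$group), table(co$patients$group))
  expect_true(all(!is.na(
    pm$patients$diagnosis_date[pm$patients$group == "case"])))
  expect_true(all(is.na(
    pm$patients$diagnosis_date[pm$patients$group == "control"])))
  # pseudo diagnosis dates sit after every event: censoring at 1 day
  # keeps the full stream
  expect_equal(nrow(censor_events(pm, 1)$events), nrow(pm$events))
})
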