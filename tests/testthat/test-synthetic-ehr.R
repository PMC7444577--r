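test_that("invalid configurations are rejected with the offending field named", {
  expect_error(ehr_config(n_cases = -1), "n_cases")
  expect_error(ehr_config(control_ratio = 0), "control_ratio")
  expect_error(ehr_config(variant_rate = 1.5), "variant_rate")
  expect_error(ehr_config(history_days = 0), "history_days")
  expect_error(ehr_config(signal_decay_days = -2), "signal_decay_days")
  bad <- data.frame(surface = "x", event_type = "TEXT_ENTITY",
                    p_case = 0.1, p_control = 0.4)
  expect_error(ehr_config(n_signal_events = 1, signal_prevalence = bad),
               "signal_prevalence")
})

test_that("an empty cohort request yields an empty cohort and ground truth", {
  gen <- generate_cohort(ehr_config(n_cases = 0, n_signal_events = 0))
  expect_equal(n_patients(gen$cohort), 0)
  expect_equal(nrow(gen$cohort$events), 0)
  expect_equal(nrow(gen$ground_truth$signal_events), 0)
  expect_length(gen$ground_truth$singleton_events, 0)
})

test_that("cohort sizes follow the matched case:control design", {
  gen <- small_gen()
  pat <- gen$cohort$patients
  expect_equal(sum(pat$group == "case"), 30)
  expect_equal(sum(pat$group == "control"), 300)
  # controls copy their matched case's age
  expect_true(all(pat$age[pat$group == "control"] %in%
                    pat$age[pat$group == "case"]))
  # cases have diagnosis dates and pre-diagnosis events, controls do not
  expect_true(all(!is.na(pat$diagnosis_date[pat$group == "case"])))
  expect_true(all(is.na(pat$diagnosis_date[pat$group == "control"])))
  ev <- gen$cohort$events
  diag <- pat$diagnosis_date[match(ev$patient_id, pat$patient_id)]
  pre <- !is.na(diag) & ev$date < diag
  expect_true(all(pat$patient_id[pat$group == "case"] %in%
                    ev$patient_id[pre]))
})

test_that("control streams are longer on average than case streams", {
  gen <- small_gen()
  tab <- table(gen$cohort$events$patient_id)
  pat <- gen$cohort$patients
  expect_gt(mean(tab[pat$patient_id[pat$group == "control"]]),
            mean(tab[pat$patient_id[pat$group == "case"]]))
})

test_that("identical configurations generate byte-identical cohorts", {
  cfg <- ehr_config(n_cases = 10, background_vocab_size = 300, seed = 5)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1, g2)
  f1 <- tempfile(); f2 <- tempfile()
  write_cohort_jsonl(g1$cohort, f1)
  write_cohort_jsonl(g2$cohort, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
})

test_that("planted prevalences are calibrated to their exact binomial intervals", {
  # the spec'd single-event check at n = 500 ...
  tab <- data.frame(surface = "markersignal", event_type = "TEXT_ENTITY",
                    p_case = 0.4, p_control = 0.01)
  gen <- generate_cohort(ehr_config(n_cases = 500, control_ratio = 2,
                                    n_signal_events = 1,
                                    signal_prevalence = tab,
                                    background_vocab_size = 300,
                                    mean_events_case = 30,
                                    mean_events_control = 45, seed = 21))
  pat <- gen$cohort$patients
  hit <- carriers(gen$cohort, gen$ground_truth, "markersignal")
  n_case_hit <- sum(pat$group[match(hit, pat$patient_id)] == "case")
  n_ctrl_hit <- sum(pat$group[match(hit, pat$patient_id)] == "control")
  ci_case <- binom_interval(500, 0.4, 0.01)
  ci_ctrl <- binom_interval(1000, 0.01, 0.01)
  expect_gte(n_case_hit, ci_case[1]); expect_lte(n_case_hit, ci_case[2])
  expect_gte(n_ctrl_hit, ci_ctrl[1]); expect_lte(n_ctrl_hit, ci_ctrl[2])

  # ... and the default 20-event table, with the interval level adjusted
  # for testing 40 intervals jointly (Bonferroni), so the familywise
  # level stays at 1%
  gen <- small_gen()
  pat <- gen$cohort$patients
  n_case <- sum(pat$group == "case"); n_ctrl <- sum(pat$group == "control")
  sig <- gen$ground_truth$signal_events
  for (j in seq_len(nrow(sig))) {
    hit <- carriers(gen$cohort, gen$ground_truth, sig$surface[j])
    grp <- pat$group[match(hit, pat$patient_id)]
    ci <- binom_interval(n_case, sig$p_case[j], 0.01 / 40)
    expect_gte(sum(grp == "case"), ci[1])
    expect_lte(sum(grp == "case"), ci[2])
    ci <- binom_interval(n_ctrl, sig$p_control[j], 0.01 / 40)
    expect_gte(sum(grp == "control"), ci[1])
    expect_lte(sum(grp == "control"), ci[2])
  }
})

test_that("corrupt_surface returns distance-1 corruptions preserving word-initial letters", {
  expect_error(corrupt_surface(""), "non-empty")
  expect_error(corrupt_surface(character(0)), "non-empty")
  set.seed(1)
  for (s in c("thyreoideacancer", "cin 3", "a", "ab",
              random_strings(50, 3, 12))) {
    out <- corrupt_surface(s)
    expect_equal(levenshtein(s, out), 1L)
    wa <- strsplit(s, " ", fixed = TRUE)[[1]]
    wb <- strsplit(out, " ", fixed = TRUE)[[1]]
    expect_equal(length(wa), length(wb))
    expect_equal(substr(wa, 1, 1), substr(wb, 1, 1))
  }
  # single character: only a first-letter-preserving insertion exists
  set.seed(2)
  out <- corrupt_surface("a")
  expect_equal(nchar(out), 2L)
  expect_equal(substr(out, 1, 1), "a")
})

test_that("injected variants are at distance 1 and share the first letter", {
  gen <- small_gen()
  vm <- gen$ground_truth$variant_map
  expect_gt(nrow(vm), 0)
  expect_true(all(levenshtein(vm$variant, vm$canonical) == 1L))
  expect_true(all(substr(vm$variant, 1, 1) == substr(vm$canonical, 1, 1)))
  # plumbing invariant: planted signals and singleton noise are disjoint
  expect_length(intersect(gen$ground_truth$signal_events$surface,
                          gen$ground_truth$singleton_events), 0)
})

test_that("ground truth and cohorts survive a serialization round trip", {
  gen <- generate_cohort(ehr_config(n_cases = 5, background_vocab_size = 200,
                                    mean_events_case = 20,
                                    mean_events_control = 30, seed = 9))
  f <- tempfile()
  write_cohort_jsonl(gen$cohort, f)
  back <- read_cohort_jsonl(f)
  p1 <- gen$cohort$patients[order(gen$cohort$patients$patient_id), ]
  p2 <- back$patients[order(back$patients$patient_id), ]
  rownames(p1) <- rownames(p2) <- NULL
  expect_equal(p1, p2)
  key <- function(e) {
    e <- e[order(e$patient_id, e$date, e$event_type, e$surface), ]
    rownames(e) <- NULL
    e
  }
  expect_equal(key(back$events)$surface, key(gen$cohort$events)$surface)
  expect_equal(key(back$events)$date, key(gen$cohort$events)$date)
  g <- tempfile()
  write_ground_truth(gen$ground_truth, g)
  gt2 <- read_ground_truth(g)
  expect_equal(gt2$signal_events$p_case,
               gen$ground_truth$signal_events$p_case)
  expect_equal(sort(gt2$singleton_events),
               sort(gen$ground_truth$singleton_events))
  unlink(c(f, g))
})
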