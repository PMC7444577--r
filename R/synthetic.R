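#' Configuration for the synthetic EHR cohort generator
#'
#' Builds a validated configuration object for [generate_cohort()].  The
#' defaults emulate the structure of a hospital case-control extraction for
#' a screening-detectable cancer: a 1:10 age-matched case:control ratio,
#' fewer recorded events for cases (whose streams stop at diagnosis) than
#' for controls, a heavy-tailed free-text vocabulary with misspelling
#' variants, negated findings/disorders, family-history note sections,
#' patient-unique noise events, lab values with reference ranges, and a set
#' of planted discriminative events whose case/control prevalence contrasts
#' follow the magnitudes seen in published top-ranked feature tables
#' (case prevalence roughly 5--44%, control prevalence well below 4%).
#'
#' @param n_cases number of cases.
#' @param control_ratio controls per case (age-matched), default 10.
#' @param n_signal_events number of planted discriminative events.
#' @param signal_prevalence optional data frame with columns `surface`,
#'   `event_type`, `p_case`, `p_control`; defaults to a built-in table of
#'   20 contrasts.  Each row must satisfy `p_case > p_control`.
#' @param background_vocab_size number of distinct background text-entity
#'   surfaces.
#' @param mean_events_case,mean_events_control mean total events per case
#'   (pre-diagnosis) and per control; the control stream is longer because
#'   it is never truncated at a diagnosis.
#' @param variant_rate probability that a text-entity occurrence is written
#'   as a distance-1 spelling corruption of its canonical surface.
#' @param negation_rate_finding,negation_rate_disorder probability that a
#'   finding (default 0.10) or disorder (default 0.06) mention is negated.
#' @param singleton_rate probability that a patient carries one
#'   patient-unique noise event.
#' @param history_days length of the recorded history window, in days.
#' @param signal_decay_days scale (days) of the exponential decay of
#'   planted case-signal timing before diagnosis; small values concentrate
#'   the signal close to the diagnosis date.
#' @param seed integer RNG seed; identical configurations generate
#'   byte-identical cohorts.
#' @return An object of class `ehr_config`.
#' @export
ehr_config <- function(n_cases = 100,
                       control_ratio = 10,
                       n_signal_events = 20,
                       signal_prevalence = NULL,
                       background_vocab_size = 6000,
                       mean_events_case = 187,
                       mean_events_control = 282,
                       variant_rate = 0.15,
                       negation_rate_finding = 0.10,
                       negation_rate_disorder = 0.06,
                       singleton_rate = 0.30,
                       history_days = 730,
                       signal_decay_days = 90,
                       seed = 1L) {
  chk_count <- function(x, name, min = 0) {
    if (length(x) != 1 || is.na(x) || x < min || x != round(x))
      stop(sprintf("invalid config field '%s'", name), call. = FALSE)
  }
  chk_prob <- function(x, name) {
    if (length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop(sprintf("invalid config field '%s'", name), call. = FALSE)
  }
  chk_pos <- function(x, name) {
    if (length(x) != 1 || is.na(x) || x <= 0)
      stop(sprintf("invalid config field '%s'", name), call. = FALSE)
  }
  chk_count(n_cases, "n_cases", min = 0)
  chk_count(control_ratio, "control_ratio", min = 1)
  chk_count(n_signal_events, "n_signal_events", min = 0)
  chk_count(background_vocab_size, "background_vocab_size", min = 1)
  chk_pos(mean_events_case, "mean_events_case")
  chk_pos(mean_events_control, "mean_events_control")
  chk_prob(variant_rate, "variant_rate")
  chk_prob(negation_rate_finding, "negation_rate_finding")
  chk_prob(negation_rate_disorder, "negation_rate_disorder")
  chk_prob(singleton_rate, "singleton_rate")
  chk_count(history_days, "history_days", min = 1)
  chk_pos(signal_decay_days, "signal_decay_days")
  chk_count(seed, "seed")

  if (is.null(signal_prevalence))
    signal_prevalence <- default_signal_table(n_signal_events)
  else
    signal_prevalence <- as.data.frame(signal_prevalence)
  need <- c("surface", "event_type", "p_case", "p_control")
  if (!all(need %in% names(signal_prevalence)))
    stop("invalid config field 'signal_prevalence': needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(signal_prevalence) != n_signal_events)
    stop("invalid config field 'signal_prevalence': needs n_signal_events rows",
         call. = FALSE)
  if (n_signal_events > 0) {
    ok <- signal_prevalence$p_case > 0 & signal_prevalence$p_case <= 1 &
      signal_prevalence$p_control >= 0 & signal_prevalence$p_control < 1 &
      signal_prevalence$p_case > signal_prevalence$p_control
    if (!all(ok))
      stop("invalid config field 'signal_prevalence': each row needs ",
           "0 < p_control < p_case <= 1", call. = FALSE)
    if (anyDuplicated(signal_prevalence$surface))
      stop("invalid config field 'signal_prevalence': duplicated surface",
           call. = FALSE)
  }
  structure(list(
    n_cases = as.integer(n_cases), control_ratio = as.integer(control_ratio),
    n_signal_events = as.integer(n_signal_events),
    signal_prevalence = signal_prevalence,
    background_vocab_size = as.integer(background_vocab_size),
    mean_events_case = mean_events_case,
    mean_events_control = mean_events_control,
    variant_rate = variant_rate,
    negation_rate_finding = negation_rate_finding,
    negation_rate_disorder = negation_rate_disorder,
    singleton_rate = singleton_rate,
    history_days = as.integer(history_days),
    signal_decay_days = signal_decay_days,
    seed = as.integer(seed)), class = "ehr_config")
}

#' Default planted-event prevalence table
#'
#' Twenty discriminative events (text entities, diagnosis codes and
#' procedure codes) with case/control prevalence contrasts of the magnitude
#' reported for top-ranked cervical-cancer predictors: mentions of the
#' cancer itself and its precursors, in-situ diagnosis codes and
#' colposcopy/conization procedures.  Diagnosis codes deliberately avoid the
#' C53 prefix so that planted controls survive cohort selection.
#'
#' @param n number of rows requested (at most 20 built-in rows; additional
#'   generic rows are appended beyond that).
#' @return Data frame with columns `surface`, `event_type`, `p_case`,
#'   `p_control`.
#' @export
default_signal_table <- function(n = 20) {
  tab <- data.frame(
    surface = c("cervixcancer", "cervixca", "mikroinvasiv", "skivepitelca",
                "cin 3", "medelhog diff", "skivepitelcancer", "invasivt vaxa",
                "skivepitelcancer in situ", "lagt diff",
                "Z031", "overvaxt", "D069", "N879", "lattbloda",
                "AV033", "LDC03", "cellforandring", "XLE00", "LDA20"),
    event_type = c(rep("TEXT_ENTITY", 10),
                   "ICD", "TEXT_ENTITY", "ICD", "ICD", "TEXT_ENTITY",
                   "PROC", "PROC", "TEXT_ENTITY", "PROC", "PROC"),
    p_case = c(0.436, 0.079, 0.098, 0.067, 0.145, 0.123, 0.316, 0.083,
               0.064, 0.098, 0.079, 0.065, 0.085, 0.089, 0.117,
               0.123, 0.052, 0.111, 0.083, 0.088),
    p_control = c(0.0035, 0.0004, 0.0004, 0.0017, 0.0057, 0.0096, 0.0096,
                  0.0083, 0.0022, 0.0065, 0.0138, 0.0102, 0.0059, 0.0062,
                  0.0223, 0.0386, 0.0091, 0.0200, 0.0125, 0.0094),
    stringsAsFactors = FALSE)
  if (n <= nrow(tab)) return(tab[seq_len(n), , drop = FALSE])
  extra <- n - nrow(tab)
  rbind(tab, data.frame(
    surface = sprintf("signalterm%02d", seq_len(extra)),
    event_type = "TEXT_ENTITY", p_case = 0.10, p_control = 0.005,
    stringsAsFactors = FALSE))
}

# Deterministic pseudo-Swedish word list with Zipf-weighted sampling
# probabilities; consonant-vowel syllable compounds, 2-4 syllables.
make_word_list <- function(n) {
  onset <- c("b", "d", "f", "g", "h", "k", "l", "m", "n", "p", "r", "s",
             "t", "v", "sk", "st", "bl", "gr")
  vowel <- c("a", "e", "i", "o", "u", "y")
  coda <- c("", "", "", "r", "n", "l", "s", "t", "k", "st")
  words <- character(0)
  while (length(words) < n) {
    k <- sample(2:4, n, replace = TRUE)
    w <- vapply(k, function(ki) {
      paste0(vapply(seq_len(ki), function(i)
        paste0(sample(onset, 1), sample(vowel, 1), sample(coda, 1)),
        character(1)), collapse = "")
    }, character(1))
    words <- unique(c(words, w))
  }
  words <- words[seq_len(n)]
  data.frame(word = words,
             weight = 1 / seq_len(n)^0.8,
             stringsAsFactors = FALSE)
}

# Background text-entity vocabulary: compounds of 1-4 Zipf-sampled words,
# giving the word-containment hierarchy a realistic top-heavy shape.
make_text_vocab <- function(words, size) {
  surfaces <- character(0)
  while (length(surfaces) < size) {
    need <- size - length(surfaces)
    wc <- sample(1:4, 2 * need + 10, replace = TRUE,
                 prob = c(0.45, 0.30, 0.17, 0.08))
    s <- vapply(wc, function(k)
      paste(sample(words$word, k, prob = words$weight), collapse = " "),
      character(1))
    surfaces <- unique(c(surfaces, s))
  }
  surfaces <- surfaces[seq_len(size)]
  data.frame(surface = surfaces,
             weight = 1 / seq_along(surfaces)^0.7,
             entity_class = sample(c("FINDING", "DISORDER"), size,
                                   replace = TRUE, prob = c(0.6, 0.4)),
             stringsAsFactors = FALSE)
}

# Embedded pools of plausible codes drawn from the shipped ICD section
# ranges; ATC codes follow the letter-digit-letter-digit shape, procedure
# codes the two-letter three-digit shape.
make_code_pools <- function() {
  roots <- c("A09", "B18", "C50", "C56", "C61", "C67", "D12", "D25", "D50",
             "E03", "E11", "E66", "F32", "F41", "G43", "G47", "H10", "I10",
             "I25", "I48", "J03", "J18", "J45", "K21", "K29", "K52", "K80",
             "L20", "L50", "M17", "M54", "M79", "N10", "N30", "N39", "N76",
             "N80", "N92", "N95", "O03", "O21", "O26", "Q51", "R07", "R10",
             "R31", "R51", "S32", "T81", "Z01", "Z12", "Z30", "Z51", "Z87")
  icd <- c(roots, paste0(rep(roots, each = 2), c("0", "9")))
  atc_letter <- c("A", "B", "C", "D", "G", "J", "L", "M", "N", "R", "S", "V")
  atc <- unique(vapply(seq_len(120), function(i)
    paste0(sample(atc_letter, 1),
           sprintf("%02d", sample(1:16, 1)),
           paste0(sample(LETTERS[1:6], 2, replace = TRUE), collapse = ""),
           sprintf("%02d", sample(1:30, 1))), character(1)))
  proc <- unique(vapply(seq_len(100), function(i)
    paste0(paste0(sample(LETTERS, 2, replace = TRUE), collapse = ""),
           sprintf("%03d", sample(0:999, 1))), character(1)))
  list(icd = icd, atc = atc, proc = proc)
}

# Lab catalogue: consistent units, fixed reference ranges.
lab_catalog <- function() {
  data.frame(
    test_id = c("Hb", "LPK", "TPK", "CRP", "Na", "K", "Krea", "ALAT",
                "ASAT", "Glukos", "HbA1c", "Alb", "Ca", "TSH", "Ferritin"),
    ref_low = c(117, 3.5, 145, 0, 137, 3.5, 45, 0.15, 0.25, 4.0, 27, 36,
                2.15, 0.4, 15),
    ref_high = c(153, 8.8, 348, 5, 145, 4.4, 90, 0.75, 0.60, 6.0, 42, 48,
                 2.50, 3.7, 150),
    stringsAsFactors = FALSE)
}

FAMILY_HEADINGS <- c("Hereditet", "Familjeanamnes")
NOTE_HEADINGS <- c("Anamnes", "Status", "Bedomning", "Aktuellt")

# Days of control follow-up past the index date, chosen so cases (whose
# records stop at diagnosis) and controls share one daily event rate:
# mean_control / (history + post) = mean_case / history.
control_post_days <- function(config) {
  max(0L, as.integer(round(
    config$history_days *
      (config$mean_events_control / config$mean_events_case - 1))))
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Corrupt a surface form by one edit
#'
#' Produces a string at whole-string Levenshtein distance exactly 1 from
#' the input while preserving the first character of every word, emulating
#' the in-word misspellings that dominate spelling variation in clinical
#' text.  The edit (substitution, deletion or insertion of a lowercase
#' letter) is drawn from the current RNG state.  For inputs where no
#' first-letter-preserving substitution or deletion exists (single-letter
#' words), an insertion is applied.
#'
#' @param surface non-empty character scalar.
#' @return A corrupted surface at edit distance 1 from `surface`.
#' @export
corrupt_surface <- function(surface) {
  if (!is.character(surface) || length(surface) != 1 || is.na(surface) ||
      !nzchar(surface))
    stop("surface must be a non-empty string")
  ch <- strsplit(surface, "", fixed = TRUE)[[1]]
  n <- length(ch)
  is_space <- ch == " "
  word_first <- c(TRUE, is_space[-n])  # char following a space starts a word
  editable <- which(!is_space & !word_first)
  # insertion goes after any non-space character (never before a word's
  # first letter, which would displace it)
  insert_after <- which(!is_space)
  ops <- c(if (length(editable)) c("sub", "del"), "ins")
  op <- if (length(ops) == 1) ops else sample(ops, 1)
  if (op == "sub") {
    i <- if (length(editable) == 1) editable else sample(editable, 1)
    ch[i] <- sample(setdiff(letters, ch[i]), 1)
  } else if (op == "del") {
    i <- if (length(editable) == 1) editable else sample(editable, 1)
    ch <- ch[-i]
  } else {
    i <- if (length(insert_after) == 1) insert_after else sample(insert_after, 1)
    ch <- append(ch, sample(letters, 1), after = i)
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic case-control EHR cohort
#'
#' Draws a seeded cohort of `n_cases` cases and `n_cases * control_ratio`
#' age-matched controls with event streams over the five supported event
#' types, and returns alongside it the ground truth needed for recovery
#' experiments: the planted signal events with their configured
#' prevalences, the map from injected spelling corruptions to their
#' intended canonical forms, and the set of patient-unique noise surfaces.
#'
#' Cases carry a diagnosis date; their events fall strictly before it, and
#' the planted signal events cluster near it (days before diagnosis are
#' exponential with scale `signal_decay_days`).  Control events are spread
#' over the `history_days` window around an index date copied from the
#' matched case and are never truncated, which reproduces the asymmetry of
#' longer control streams.
#'
#' @param config an [ehr_config()].
#' @return A list with elements `cohort` (an [ehr_cohort()]) and
#'   `ground_truth` (an `ehr_ground_truth`: `signal_events`,
#'   `variant_map`, `singleton_events`).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "ehr_config")) stop("config must be an ehr_config")
  if (config$n_cases == 0) {
    empty_pat <- data.frame(patient_id = character(0), group = character(0),
                            age = numeric(0),
                            diagnosis_date = as.Date(character(0)))
    empty_ev <- data.frame(patient_id = character(0), event_type = character(0),
                           surface = character(0), date = as.Date(character(0)))
    gt <- structure(list(
      signal_events = config$signal_prevalence[0, , drop = FALSE],
      variant_map = data.frame(variant = character(0), canonical = character(0)),
      singleton_events = character(0)), class = "ehr_ground_truth")
    return(list(cohort = ehr_cohort(empty_pat, empty_ev), ground_truth = gt))
  }
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n_cases <- config$n_cases
  n_controls <- n_cases * config$control_ratio
  study_end <- as.Date("2014-12-31")
  hist <- config$history_days

  case_id <- sprintf("case_%05d", seq_len(n_cases))
  ctrl_id <- sprintf("ctrl_%06d", seq_len(n_controls))
  case_age <- sample(25:70, n_cases, replace = TRUE)
  diag_date <- study_end - sample.int(3 * 365, n_cases, replace = TRUE)
  match_idx <- rep(seq_len(n_cases), each = config$control_ratio)

  patients <- data.frame(
    patient_id = c(case_id, ctrl_id),
    group = rep(c("case", "control"), c(n_cases, n_controls)),
    age = c(case_age, case_age[match_idx]),
    diagnosis_date = c(diag_date, as.Date(rep(NA, n_controls))),
    stringsAsFactors = FALSE)

  words <- make_word_list(400)
  vocab <- make_text_vocab(words, config$background_vocab_size)
  sig <- config$signal_prevalence
  # planted text surfaces must not collide with background surfaces
  vocab <- vocab[!vocab$surface %in% sig$surface, , drop = FALSE]
  pools <- make_code_pools()
  pools$icd <- setdiff(pools$icd, sig$surface[sig$event_type == "ICD"])
  pools$proc <- setdiff(pools$proc, sig$surface[sig$event_type == "PROC"])
  pools$atc <- setdiff(pools$atc, sig$surface[sig$event_type == "ATC"])
  labs <- lab_catalog()

  ## ---- background events --------------------------------------------
  # per-patient documentation intensity: real EHR volumes are heavily
  # overdispersed, so totals are Poisson mixed over a gamma multiplier
  intensity <- stats::rgamma(n_cases + n_controls, shape = 2, rate = 2)
  n_ev <- c(pmax(rpois(n_cases, config$mean_events_case *
                         intensity[seq_len(n_cases)]), 1L),
            pmax(rpois(n_controls, config$mean_events_control *
                         intensity[n_cases + seq_len(n_controls)]), 1L))
  pid <- rep(patients$patient_id, n_ev)
  anchor <- rep(c(diag_date, diag_date[match_idx]), n_ev)
  is_case_ev <- rep(patients$group == "case", n_ev)
  n_total <- length(pid)
  type <- sample(EVENT_TYPES, n_total, replace = TRUE,
                 prob = c(0.55, 0.12, 0.10, 0.08, 0.15))
  surface <- character(n_total)
  i_txt <- which(type == "TEXT_ENTITY")
  surface[i_txt] <- sample(vocab$surface, length(i_txt), replace = TRUE,
                           prob = vocab$weight)
  for (tp in c("ICD", "ATC", "PROC")) {
    idx <- which(type == tp)
    pool <- pools[[tolower(tp)]]
    surface[idx] <- sample(pool, length(idx), replace = TRUE,
                           prob = 1 / seq_along(pool)^0.8)
  }
  i_lab <- which(type == "LAB")
  lab_row <- sample.int(nrow(labs), length(i_lab), replace = TRUE)
  surface[i_lab] <- labs$test_id[lab_row]
  # case events precede diagnosis; control streams continue past the
  # matched case's index date (they are never truncated), over a window
  # sized so the two groups share one underlying daily event rate
  post <- control_post_days(config)
  offset <- integer(n_total)
  offset[is_case_ev] <- sample.int(hist, sum(is_case_ev), replace = TRUE)
  offset[!is_case_ev] <- sample(seq(-post, hist), sum(!is_case_ev),
                                replace = TRUE)
  date <- anchor - offset

  ev <- data.frame(patient_id = pid, event_type = type, surface = surface,
                   date = date, stringsAsFactors = FALSE)
  ev$entity_class <- NA_character_
  cls <- vocab$entity_class[match(surface[i_txt], vocab$surface)]
  ev$entity_class[i_txt] <- cls
  ev$negated <- NA
  neg_rate <- ifelse(cls == "FINDING", config$negation_rate_finding,
                     config$negation_rate_disorder)
  ev$negated[i_txt] <- runif(length(i_txt)) < neg_rate
  ev$section_heading <- NA_character_
  ev$section_heading[i_txt] <- sample(
    c(NOTE_HEADINGS, FAMILY_HEADINGS, NA_character_),
    length(i_txt), replace = TRUE,
    prob = c(0.38, 0.28, 0.18, 0.06, 0.02, 0.01, 0.07))
  ev$test_id <- NA_character_
  ev$value <- NA_real_
  ev$ref_low <- NA_real_
  ev$ref_high <- NA_real_
  ev$test_id[i_lab] <- labs$test_id[lab_row]
  ev$ref_low[i_lab] <- labs$ref_low[lab_row]
  ev$ref_high[i_lab] <- labs$ref_high[lab_row]
  mid <- (labs$ref_low[lab_row] + labs$ref_high[lab_row]) / 2
  span <- labs$ref_high[lab_row] - labs$ref_low[lab_row]
  ev$value[i_lab] <- rnorm(length(i_lab), mid, span / 4)

  ## ---- planted signal events ----------------------------------------
  sig_parts <- vector("list", nrow(sig))
  for (j in seq_len(nrow(sig))) {
    has_case <- which(runif(n_cases) < sig$p_case[j])
    occ_case <- if (length(has_case)) 1L + rpois(length(has_case), 0.7) else integer(0)
    has_ctrl <- which(runif(n_controls) < sig$p_control[j])
    occ_ctrl <- if (length(has_ctrl)) 1L + rpois(length(has_ctrl), 0.3) else integer(0)
    n_oc <- sum(occ_case)
    n_ot <- sum(occ_ctrl)
    if (n_oc + n_ot == 0) next
    days_before <- pmin(ceiling(rexp(n_oc, 1 / config$signal_decay_days)), hist)
    sp <- data.frame(
      patient_id = c(rep(case_id[has_case], occ_case),
                     rep(ctrl_id[has_ctrl], occ_ctrl)),
      event_type = sig$event_type[j],
      surface = sig$surface[j],
      date = c(rep(diag_date[has_case], occ_case) - days_before,
               rep(diag_date[match_idx][has_ctrl], occ_ctrl) -
                 sample(seq(-control_post_days(config), hist), n_ot,
                        replace = TRUE)),
      stringsAsFactors = FALSE)
    sp$entity_class <- if (sig$event_type[j] == "TEXT_ENTITY") "DISORDER" else NA_character_
    sp$negated <- if (sig$event_type[j] == "TEXT_ENTITY") FALSE else NA
    sp$section_heading <- if (sig$event_type[j] == "TEXT_ENTITY")
      sample(NOTE_HEADINGS, nrow(sp), replace = TRUE) else NA_character_
    sp$test_id <- NA_character_
    sp$value <- NA_real_
    sp$ref_low <- NA_real_
    sp$ref_high <- NA_real_
    sig_parts[[j]] <- sp
  }
  ev <- rbind(ev, do.call(rbind, sig_parts))

  ## ---- spelling variants --------------------------------------------
  variant_map <- data.frame(variant = character(0), canonical = character(0),
                            stringsAsFactors = FALSE)
  if (config$variant_rate > 0) {
    i_txt_all <- which(ev$event_type == "TEXT_ENTITY")
    uniq <- unique(ev$surface[i_txt_all])
    taken <- c(uniq, sig$surface)
    var_of <- list()
    for (s in uniq) {
      vs <- character(0)
      for (k in 1:2) {
        for (att in 1:20) {
          cand <- corrupt_surface(s)
          if (!cand %in% taken) { vs <- c(vs, cand); taken <- c(taken, cand); break }
        }
      }
      if (length(vs)) var_of[[s]] <- vs
    }
    hit <- i_txt_all[runif(length(i_txt_all)) < config$variant_rate]
    hit <- hit[ev$surface[hit] %in% names(var_of)]
    if (length(hit)) {
      repl <- vapply(ev$surface[hit], function(s) {
        vs <- var_of[[s]]
        if (length(vs) == 1) vs else sample(vs, 1)
      }, character(1), USE.NAMES = FALSE)
      ev$surface[hit] <- repl
    }
    used <- unlist(var_of, use.names = FALSE)
    canon <- rep(names(var_of), lengths(var_of))
    keep <- used %in% unique(ev$surface)
    variant_map <- data.frame(variant = used[keep], canonical = canon[keep],
                              stringsAsFactors = FALSE)
  }

  ## ---- patient-unique singleton noise -------------------------------
  singleton <- character(0)
  if (config$singleton_rate > 0) {
    hit <- which(runif(nrow(patients)) < config$singleton_rate)
    if (length(hit)) {
      singleton <- vapply(hit, function(i)
        paste(sample(letters, sample(8:12, 1), replace = TRUE), collapse = ""),
        character(1))
      dup <- duplicated(singleton) | singleton %in% ev$surface
      hit <- hit[!dup]; singleton <- singleton[!dup]
      anchor_s <- ifelse(is.na(patients$diagnosis_date[hit]),
                         diag_date[match_idx][pmax(hit - n_cases, 1)],
                         patients$diagnosis_date[hit])
      sg <- data.frame(
        patient_id = patients$patient_id[hit],
        event_type = "TEXT_ENTITY", surface = singleton,
        date = as.Date(anchor_s, origin = "1970-01-01") -
          sample.int(hist, length(hit), replace = TRUE),
        entity_class = "FINDING", negated = FALSE,
        section_heading = NA_character_, test_id = NA_character_,
        value = NA_real_, ref_low = NA_real_, ref_high = NA_real_,
        stringsAsFactors = FALSE)
      ev <- rbind(ev, sg)
    }
  }

  ord <- order(ev$patient_id, ev$date, ev$event_type, ev$surface,
               method = "radix")
  ev <- ev[ord, ]
  rownames(ev) <- NULL

  gt <- structure(list(signal_events = sig, variant_map = variant_map,
                       singleton_events = singleton),
                  class = "ehr_ground_truth")
  list(cohort = ehr_cohort(patients, ev), ground_truth = gt)
}

#' @exportS3Method print ehr_ground_truth
print.ehr_ground_truth <- function(x, ...) {
  cat(sprintf("<ehr_ground_truth> %d signal events, %d variants, %d singletons\n",
              nrow(x$signal_events), nrow(x$variant_map),
              length(x$singleton_events)))
  invisible(x)
}

#' Serialize generator ground truth as JSON
#' @param gt an `ehr_ground_truth`.
#' @param path file path.
#' @return `path`, invisibly (writer); an `ehr_ground_truth` (reader).
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(unclass(gt), path, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$signal_events <- as.data.frame(x$signal_events)
  x$variant_map <- as.data.frame(x$variant_map)
  x$singleton_events <- as.character(x$singleton_events)
  structure(x, class = "ehr_ground_truth")
}
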