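test_that("confusion metrics match their definitions", {
  expect_equal(metrics_from_confusion(10, 0, 90, 0),
               c(precision = 1, recall = 1, f1 = 1, specificity = 1))
  expect_equal(metrics_from_confusion(0, 0, 90, 10),
               c(precision = 0, recall = 0, f1 = 0, specificity = 1))
  set.seed(71)
  for (i in 1:50) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1)
    tn <- sample(1:20, 1); fn <- sample(0:20, 1)
    if (tp + fn == 0) fn <- 1
    m <- metrics_from_confusion(tp, fp, tn, fn)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- tp / (tp + fn)
    expect_equal(unname(m["precision"]), p)
    expect_equal(unname(m["recall"]), r)
    expect_equal(unname(m["specificity"]), tn / (tn + fp))
    if (p + r > 0)
      expect_equal(unname(m["f1"]), 2 * p * r / (p + r))
    # F1 is the harmonic mean of the stored precision and recall
    if (p > 0 && r > 0)
      expect_equal(unname(m["f1"]), 2 / (1 / p + 1 / r), tolerance = 1e-9)
  }
  expect_error(metrics_from_confusion(0, 0, 5, 0), "positive")
  expect_error(metrics_from_confusion(5, 0, 0, 0), "negative")
  expect_error(metrics_from_confusion(-1, 0, 5, 5))
})

test_that("average AUC is the arithmetic mean over classifiers", {
  expect_equal(average_auc(c(1, 1, 1, 1)), 1)
  expect_equal(average_auc(c(0.6, 0.7, 0.8, 0.9)), 0.75)
  a <- c(0.61, 0.72, 0.83, 0.94)
  expect_equal(average_auc(a), sum(a) / 4)
  expect_error(average_auc(numeric(0)))
})

test_that("classifier specs bind encodings as configured", {
  expect_equal(classifier_spec("RF")$encoding, "count")
  expect_equal(classifier_spec("CNB")$encoding, "count")
  expect_equal(classifier_spec("BNB")$encoding, "binary")
  expect_equal(classifier_spec("SVM")$encoding, "l2norm")
  expect_equal(classifier_spec("SVM")$select_percent, 1)
  expect_equal(classifier_spec("RF")$select_percent, 10)
  specs <- default_classifier_specs()
  expect_equal(vapply(specs, `[[`, character(1), "name"),
               c("RF", "CNB", "BNB", "SVM"))
})

separable_fixture <- function(n_features = 1) {
  tab <- data.frame(surface = "pathognomonic", event_type = "TEXT_ENTITY",
                    p_case = 1.0, p_control = 0)
  gen <- generate_cohort(ehr_config(n_cases = 20, control_ratio = 5,
                                    n_signal_events = 1,
                                    signal_prevalence = tab,
                                    background_vocab_size = 200,
                                    mean_events_case = 20,
                                    mean_events_control = 30,
                                    variant_rate = 0, seed = 72))
  fm <- build_matrix(censor_events(select_cohort(gen$cohort), 1))
  extra <- character(0)
  if (n_features > 1) {
    df <- Matrix::colSums(fm$matrix > 0)
    df <- df[names(df) != "TEXT:L1:pathognomonic"]
    extra <- names(sort(df, decreasing = TRUE))[seq_len(n_features - 1)]
  }
  restrict_features(fm, c("TEXT:L1:pathognomonic", extra))
}

test_that("a perfectly separable cohort is classified perfectly", {
  fm <- separable_fixture()
  for (name in c("RF", "BNB", "SVM")) {
    enc <- classifier_spec(name)$encoding
    res <- crossvalidate(set_encoding(fm, enc), classifier_spec(name),
                         seed = 72, n_folds = 5)
    expect_equal(res$auc, 1, info = name)
    expect_equal(res$specificity, 1, info = name)
  }
  # complement naive Bayes needs at least two multinomial cells to carry
  # information; hand it a two-feature matrix with disjoint case/control
  # vocabularies, the separable case for a multinomial model
  set.seed(73)
  n1 <- 10; n0 <- 50
  m <- Matrix::sparseMatrix(
    i = seq_len(n1 + n0), j = rep(c(1L, 2L), c(n1, n0)),
    x = rpois(n1 + n0, 2) + 1, dims = c(n1 + n0, 2))
  dimnames(m) <- list(sprintf("p%02d", seq_len(n1 + n0)),
                      c("TEXT:L1:signalword", "TEXT:L1:bakgrund"))
  fm2 <- structure(list(
    matrix = m,
    patients = data.frame(patient_id = rownames(m),
                          group = rep(c("case", "control"), c(n1, n0))),
    features = data.frame(feature = colnames(m), event_type = "TEXT",
                          level = "L1"),
    encoding = "count"), class = "ehr_feature_matrix")
  res <- crossvalidate(fm2, classifier_spec("CNB"), seed = 72, n_folds = 5)
  expect_equal(res$auc, 1)
  expect_equal(res$specificity, 1)
})

test_that("cross-validation folds partition patients and respect the seed", {
  co <- select_cohort(small_gen()$cohort)
  fm <- build_matrix(censor_events(co, 1))
  res1 <- crossvalidate(fm, classifier_spec("CNB"), seed = 5)
  res2 <- crossvalidate(fm, classifier_spec("CNB"), seed = 5)
  expect_identical(res1$folds, res2$folds)
  expect_equal(nrow(res1$folds), 10)
  expect_equal(res1$n_cases, 30)
  expect_equal(res1$n_controls, 300)
  # folds partition patients (internal helper)
  fold <- ehrmine:::make_folds(fm$patients$group, 10, 5)
  expect_length(fold, 330)
  expect_equal(sort(unique(fold)), 1:10)
  expect_true(all(table(fold, fm$patients$group)[, "case"] == 3))
})

test_that("a fold with a single class raises an informative error", {
  fm <- separable_fixture()
  # 20 cases cannot stratify into 25 folds
  expect_error(crossvalidate(fm, classifier_spec("CNB"), n_folds = 25),
               "single class")
})

test_that("feature selection is blind to test-partition labels", {
  gen <- small_gen()
  prep <- preprocess_cohort(select_cohort(gen$cohort))
  sp <- split_dev_test(prep$cohort, 0.3, seed = 7)
  rk1 <- rank_features(build_matrix(censor_events(sp$dev, 1)), "ttest")
  # permute the test partition's labels; the dev ranking must not move
  test_perm <- permute_labels(sp$test, seed = 8)
  rk2 <- rank_features(build_matrix(censor_events(sp$dev, 1)), "ttest")
  expect_identical(rk1$scores, rk2$scores)
  # and the selected feature list is identical
  expect_identical(select_top(rk1, 10), select_top(rk2, 10))
})

test_that("the sweep yields one result row per classifier and cutoff", {
  gen <- small_gen()
  prep <- preprocess_cohort(select_cohort(gen$cohort))
  sp <- split_dev_test(prep$cohort, 0.3, seed = 7)
  specs <- list(classifier_spec("CNB"), classifier_spec("BNB"))
  res <- sweep_evaluation(sp$dev, sp$test, specs = specs,
                          cutoffs = c(1L, 194L), n_folds = 5, seed = 7)
  expect_equal(nrow(res), 4)  # 2 cutoffs x 2 classifiers
  expect_equal(res$cutoff_days, c(1L, 1L, 194L, 194L))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  expect_true(all(res$specificity >= 0 & res$specificity <= 1))
  details <- attr(res, "details")
  expect_length(details, 4)
  # stored fold AUCs average to the reported AUC
  d1 <- details[[1]]
  expect_equal(mean(d1$folds$auc), d1$auc)
})
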