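#' Classifier configuration
#'
#' Binds each classifier to its input encoding: random forest (`RF`) and
#' complement naive Bayes (`CNB`) consume raw counts, Bernoulli naive
#' Bayes (`BNB`) binary indicators, and the linear support vector machine
#' (`SVM`) L2-normalized counts.  The default feature-selection fraction
#' is the top 10% of informative features, except the SVM which uses the
#' top 1%.
#'
#' @param name one of `"RF"`, `"CNB"`, `"BNB"`, `"SVM"`.
#' @param select_percent top fraction (in percent) of informative
#'   features to train on; `NULL` for the per-classifier default.
#' @param hyper named list passed to the underlying implementation
#'   (`num.trees` for RF, `cost` for SVM, `alpha` for the naive Bayes
#'   smoothers).
#' @return A list of class `ehr_classifier_spec`.
#' @export
classifier_spec <- function(name = c("RF", "CNB", "BNB", "SVM"),
                            select_percent = NULL, hyper = list()) {
  name <- match.arg(name)
  encoding <- switch(name, RF = "count", CNB = "count", BNB = "binary",
                     SVM = "l2norm")
  if (is.null(select_percent))
    select_percent <- if (name == "SVM") 1 else 10
  structure(list(name = name, encoding = encoding,
                 select_percent = select_percent, hyper = hyper),
            class = "ehr_classifier_spec")
}

#' The four default classifier configurations
#' @return List of [classifier_spec()] objects (RF, CNB, BNB, SVM).
#' @export
default_classifier_specs <- function() {
  lapply(c("RF", "CNB", "BNB", "SVM"), classifier_spec)
}

#' Confusion-matrix metrics
#'
#' @param tp,fp,tn,fn non-negative counts; at least one actual positive
#'   (`tp + fn >= 1`) and one actual negative (`tn + fp >= 1`) are
#'   required.
#' @return Named numeric vector: `precision` (0 when nothing is
#'   predicted positive), `recall` (= sensitivity), `f1` (0 when
#'   precision + recall = 0) and `specificity`.
#' @export
metrics_from_confusion <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative")
  if (tp + fn < 1) stop("need at least one actual positive")
  if (tn + fp < 1) stop("need at least one actual negative")
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  specificity <- tn / (tn + fp)
  c(precision = precision, recall = recall, f1 = f1,
    specificity = specificity)
}

#' Average AUC across classifiers
#'
#' The per-configuration summary used when comparing event types or
#' representation levels: the sum of the individual classifiers' AUCs
#' divided by the number of classifiers.
#'
#' @param aucs numeric vector of AUC values (one per classifier).
#' @return Their arithmetic mean.
#' @export
average_auc <- function(aucs) {
  if (!length(aucs)) stop("no AUC values to average")
  mean(aucs)
}

## ---- classifier back-ends -------------------------------------------

# Stratified k-fold assignment; every fold gets (nearly) the class
# proportions of the whole set.
make_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (g in unique(labels)) {
      idx <- sample(which(labels == g))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

fit_predict <- function(spec, x_train, y_train, x_test, seed) {
  switch(spec$name,
    RF = {
      nt <- spec$hyper$num.trees %||% 500
      fit <- ranger::ranger(x = as.matrix(x_train),
                            y = factor(y_train, c("control", "case")),
                            num.trees = nt, probability = TRUE,
                            seed = seed, num.threads = 1)
      p <- predict(fit, data = as.matrix(x_test),
                   num.threads = 1)$predictions[, "case"]
      list(score = p, label = ifelse(p >= 0.5, "case", "control"))
    },
    CNB = {
      fit <- cnb_fit(x_train, y_train, alpha = spec$hyper$alpha %||% 1)
      s <- cnb_score(fit, x_test)
      list(score = s, label = ifelse(s > 0, "case", "control"))
    },
    BNB = {
      fit <- bnb_fit(x_train, y_train, alpha = spec$hyper$alpha %||% 1)
      s <- bnb_score(fit, x_test)
      list(score = s, label = ifelse(s > 0, "case", "control"))
    },
    SVM = {
      fit <- e1071::svm(x = as.matrix(x_train),
                        y = factor(y_train, c("control", "case")),
                        kernel = "linear", cost = spec$hyper$cost %||% 1,
                        scale = FALSE)
      pr <- predict(fit, as.matrix(x_test), decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      # orient the margin so positive means "case"
      if (grepl("^control", colnames(attr(pr, "decision.values"))[1]))
        dv <- -dv
      list(score = dv, label = as.character(pr))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Complement naive Bayes (count data): each class is scored against the
# smoothed feature distribution of its complement, which is robust under
# heavy class imbalance.  Binary specialisation; the score is the
# difference of the complement log-likelihood terms.
cnb_fit <- function(x, y, alpha = 1) {
  x <- methods::as(x, "CsparseMatrix")
  is_case <- y == "case"
  n_case_f <- Matrix::colSums(x[is_case, , drop = FALSE])
  n_ctrl_f <- Matrix::colSums(x[!is_case, , drop = FALSE])
  V <- ncol(x)
  # theta of the complement class
  th_case <- (alpha + n_ctrl_f) / (alpha * V + sum(n_ctrl_f))
  th_ctrl <- (alpha + n_case_f) / (alpha * V + sum(n_case_f))
  list(w = -log(th_case) - (-log(th_ctrl)))
}

cnb_score <- function(fit, x) {
  # jll_case - jll_ctrl = x . (-log th_case + log th_ctrl); higher = case
  drop(methods::as(x, "CsparseMatrix") %*% fit$w)
}

# Bernoulli naive Bayes on presence/absence with Laplace smoothing.
bnb_fit <- function(x, y, alpha = 1) {
  x <- methods::as(x, "CsparseMatrix")
  is_case <- y == "case"
  n1 <- sum(is_case); n0 <- sum(!is_case)
  p1 <- (Matrix::colSums(x[is_case, , drop = FALSE] > 0) + alpha) /
    (n1 + 2 * alpha)
  p0 <- (Matrix::colSums(x[!is_case, , drop = FALSE] > 0) + alpha) /
    (n0 + 2 * alpha)
  list(w = log(p1) - log(p0) - log(1 - p1) + log(1 - p0),
       b = log(n1 / n0) + sum(log(1 - p1) - log(1 - p0)))
}

bnb_score <- function(fit, x) {
  xb <- methods::as(x, "CsparseMatrix")
  xb@x <- rep(1, length(xb@x))
  drop(xb %*% fit$w) + fit$b
}

fold_auc <- function(labels, scores) {
  as.numeric(pROC::auc(response = labels, predictor = scores,
                       levels = c("control", "case"), direction = "<",
                       quiet = TRUE))
}

#' Cross-validated evaluation of one classifier
#'
#' Stratified patient-level k-fold cross-validation (default 10-fold) of
#' a classifier configuration on a feature matrix: in each round 90% of
#' the patients train the classifier and the held-out 10% are scored.
#' Per-fold AUC is computed from the continuous scores; precision,
#' recall, F1 and specificity come from the label predictions at the
#' classifier's default decision rule.  The summary metrics pool the
#' fold confusion matrices (so F1 stays the harmonic mean of the stored
#' precision and recall), while AUC is the mean of the fold AUCs.
#'
#' @param fm an `ehr_feature_matrix` in the classifier's encoding.
#' @param spec a [classifier_spec()].
#' @param seed integer seed controlling fold assignment and classifier
#'   randomness.
#' @param n_folds number of folds (default 10).
#' @param cutoff_days optional horizon annotation carried into the
#'   result.
#' @return An object of class `ehr_eval_result`: classifier name,
#'   `cutoff_days`, summary `auc`, `precision`, `recall`, `f1`,
#'   `specificity`, a `folds` data frame of per-fold values, and the
#'   group sizes.
#' @export
crossvalidate <- function(fm, spec, seed = 1L, n_folds = 10,
                          cutoff_days = NA_integer_) {
  stopifnot(inherits(fm, "ehr_feature_matrix"),
            inherits(spec, "ehr_classifier_spec"))
  labels <- fm$patients$group
  fold <- make_folds(labels, n_folds, seed)
  for (f in seq_len(n_folds)) {
    if (length(unique(labels[fold == f])) < 2 ||
        length(unique(labels[fold != f])) < 2)
      stop("a fold contains a single class; enlarge the cohort or reduce n_folds")
  }
  m <- fm$matrix
  folds <- data.frame(fold = seq_len(n_folds), auc = NA_real_,
                      precision = NA_real_, recall = NA_real_,
                      f1 = NA_real_, specificity = NA_real_)
  conf <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (f in seq_len(n_folds)) {
    te <- fold == f
    pred <- fit_predict(spec, m[!te, , drop = FALSE], labels[!te],
                        m[te, , drop = FALSE], seed = seed + f)
    truth <- labels[te]
    folds$auc[f] <- fold_auc(truth, pred$score)
    tp <- sum(pred$label == "case" & truth == "case")
    fp <- sum(pred$label == "case" & truth == "control")
    tn <- sum(pred$label == "control" & truth == "control")
    fn <- sum(pred$label == "control" & truth == "case")
    conf <- conf + c(tp = tp, fp = fp, tn = tn, fn = fn)
    folds[f, c("precision", "recall", "f1", "specificity")] <-
      metrics_from_confusion(tp, fp, tn, fn)
  }
  met <- metrics_from_confusion(unname(conf["tp"]), unname(conf["fp"]),
                                unname(conf["tn"]), unname(conf["fn"]))
  structure(list(classifier = spec$name, cutoff_days = cutoff_days,
                 auc = mean(folds$auc),
                 precision = unname(met["precision"]),
                 recall = unname(met["recall"]),
                 f1 = unname(met["f1"]),
                 specificity = unname(met["specificity"]),
                 folds = folds,
                 n_cases = sum(labels == "case"),
                 n_controls = sum(labels == "control")),
            class = "ehr_eval_result")
}

#' @exportS3Method print ehr_eval_result
print.ehr_eval_result <- function(x, ...) {
  cat(sprintf(
    "<ehr_eval_result> %s%s: AUC %.3f, P %.3f, R %.3f, F1 %.3f, spec %.3f\n",
    x$classifier,
    if (is.na(x$cutoff_days)) "" else sprintf(" @ %d days", x$cutoff_days),
    x$auc, x$precision, x$recall, x$f1, x$specificity))
  invisible(x)
}

as_row <- function(res) {
  data.frame(classifier = res$classifier, cutoff_days = res$cutoff_days,
             auc = res$auc, precision = res$precision, recall = res$recall,
             f1 = res$f1, specificity = res$specificity,
             n_cases = res$n_cases, n_controls = res$n_controls,
             stringsAsFactors = FALSE)
}

#' Evaluate classifiers across a censoring grid
#'
#' The full time-censored experiment: for every cutoff the development
#' partition is censored, a feature ranking is fitted on it, each
#' classifier trains on its top-ranked features, and the censored test
#' partition is evaluated by stratified cross-validation.  Feature
#' selection never sees the test partition.
#'
#' @param dev,test development and test [ehr_cohort()]s (already
#'   preprocessed: normalized, policies applied, rare events pruned).
#' @param specs list of [classifier_spec()]s.
#' @param cutoffs integer vector of horizons (days before diagnosis).
#' @param rep_config an [ehr_representation()].
#' @param ranking_method filter score for feature selection.
#' @param seed integer seed.
#' @param n_folds folds for [crossvalidate()].
#' @param config_label optional label recorded in the result rows (used
#'   when sweeping over representations).
#' @return A data frame of class `ehr_sweep`, one row per (cutoff,
#'   classifier), sorted by cutoff then classifier, with the summary
#'   metrics and an attribute `"details"` holding the
#'   `ehr_eval_result`s.
#' @export
sweep_evaluation <- function(dev, test, specs = default_classifier_specs(),
                             cutoffs = default_censor_grid(),
                             rep_config = ehr_representation(),
                             ranking_method = "ttest",
                             seed = 1L, n_folds = 10,
                             config_label = "default") {
  rows <- list()
  details <- list()
  for (cut in cutoffs) {
    dev_c <- censor_events(dev, cut)
    test_c <- censor_events(test, cut)
    fm_dev <- build_matrix(dev_c, rep_config, "count")
    ranking <- rank_features(fm_dev, ranking_method)
    fm_test_count <- build_matrix(test_c, rep_config, "count")
    for (spec in specs) {
      sel <- select_top(ranking, spec$select_percent)
      fm <- restrict_features(fm_test_count, sel)
      if (ncol(fm$matrix) == 0)
        stop("no selected feature is present in the test partition")
      fm <- set_encoding(fm, spec$encoding)
      res <- crossvalidate(fm, spec, seed = seed, n_folds = n_folds,
                           cutoff_days = cut)
      row <- as_row(res)
      row$config <- config_label
      rows[[length(rows) + 1]] <- row
      details[[sprintf("%s_%d_%s", config_label, cut, spec$name)]] <- res
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cutoff_days, out$classifier), ]
  rownames(out) <- NULL
  attr(out, "details") <- details
  class(out) <- c("ehr_sweep", class(out))
  out
}

#' Sweep over alternative representations
#'
#' Runs [sweep_evaluation()] once per named representation configuration
#' (e.g. one event type at a time, or one hierarchy level at a time) and
#' stacks the results, enabling average-AUC comparisons across event
#' types and levels.
#'
#' @param dev,test preprocessed cohorts.
#' @param configs named list of [ehr_representation()] objects.
#' @param ... passed to [sweep_evaluation()].
#' @return A combined `ehr_sweep` data frame with a `config` column.
#' @export
sweep_representations <- function(dev, test, configs, ...) {
  out <- lapply(names(configs), function(nm)
    sweep_evaluation(dev, test, rep_config = configs[[nm]],
                     config_label = nm, ...))
  res <- do.call(rbind, lapply(out, as.data.frame))
  class(res) <- c("ehr_sweep", "data.frame")
  res
}
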