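#' Two-sample t statistic for one feature column
#'
#' Absolute pooled-variance (Student) two-sample t statistic between case
#' and control count values; high scores go to features with different
#' group means and low within-group variance.  The pooled form is used
#' deliberately: under heavy class imbalance the Welch statistic hands
#' its largest values to rare features seen only in the majority group
#' (whose group standard error is tiny), whereas the pooled statistic
#' ranks case-enriched prevalence contrasts first -- which is the
#' behaviour this ranking exists to provide.  When both group variances
#' are zero and the means agree the score is 0; when the means differ
#' with zero pooled variance the statistic is infinite and is capped at
#' the largest finite double so that scores stay finite and sortable.
#'
#' @param x numeric vector of per-patient values for one feature.
#' @param labels character/factor vector with values `"case"` and
#'   `"control"`.
#' @return Non-negative scalar.
#' @export
ttest_score <- function(x, labels) {
  case <- x[labels == "case"]
  ctrl <- x[labels == "control"]
  n1 <- length(case); n0 <- length(ctrl)
  if (!n1 || !n0) stop("both groups must be non-empty")
  sp2 <- ((n1 - 1) * stats::var(case) + (n0 - 1) * stats::var(ctrl)) /
    (n1 + n0 - 2)
  se2 <- sp2 * (1 / n1 + 1 / n0)
  d <- abs(mean(case) - mean(ctrl))
  if (se2 == 0) return(if (d == 0) 0 else .Machine$double.xmax)
  min(d / sqrt(se2), .Machine$double.xmax)
}

#' Mutual information between feature presence and the class label
#'
#' Plug-in mutual information (natural log) of the 2x2 empirical joint
#' distribution of the binarized feature and the case/control label,
#' with the convention `0 * log 0 = 0`.
#'
#' @inheritParams ttest_score
#' @return Non-negative scalar (nats).
#' @export
mi_score <- function(x, labels) {
  if (!any(labels == "case") || !any(labels == "control"))
    stop("both groups must be non-empty")
  tab <- cells2x2(x > 0, labels == "case")
  mi_from_cells(tab["a"], tab["b"], tab["c"], tab["d"])
}

#' Pearson chi-square score of feature presence versus the class label
#'
#' Chi-square statistic of the 2x2 presence-by-label table without
#' continuity correction; features that are constant (present for
#' everyone or no one) score 0.
#'
#' @inheritParams ttest_score
#' @return Non-negative scalar.
#' @export
chi2_score <- function(x, labels) {
  if (!any(labels == "case") || !any(labels == "control"))
    stop("both groups must be non-empty")
  tab <- cells2x2(x > 0, labels == "case")
  chi2_from_cells(tab["a"], tab["b"], tab["c"], tab["d"])
}

# a = present&case, b = absent&case, c = present&control, d = absent&control
cells2x2 <- function(present, is_case) {
  c(a = sum(present & is_case), b = sum(!present & is_case),
    c = sum(present & !is_case), d = sum(!present & !is_case))
}

mi_from_cells <- function(a, b, c, d) {
  n <- a + b + c + d
  p <- c(a, b, c, d) / n
  px <- c(a + c, b + d) / n   # present / absent
  py <- c(a + b, c + d) / n   # case / control
  ex <- c(px[1] * py[1], px[2] * py[1], px[1] * py[2], px[2] * py[2])
  terms <- ifelse(p > 0, p * log(p / ex), 0)
  max(sum(terms), 0)
}

chi2_from_cells <- function(a, b, c, d) {
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(0)
  unname(n * (a * d - b * c)^2 / denom)
}

#' Rank all features of a matrix by a filter score
#'
#' Scores every feature column against the case/control label and orders
#' them by decreasing score, ties broken by feature identifier, so that
#' rankings are reproducible.  The t-test operates on the count values;
#' mutual information and chi-square operate on presence/absence, which
#' is what their 2x2 tables require.  The *informative set* is the
#' features with strictly positive score.
#'
#' @param fm an `ehr_feature_matrix` (count encoding recommended; MI and
#'   chi-square binarize internally).
#' @param method `"ttest"`, `"mi"` or `"chi2"`.
#' @return An object of class `ehr_ranking`: data frame `scores`
#'   (`feature`, `event_type`, `level`, `score`, ordered), `informative`
#'   (character vector, descending score) and `method`.
#' @export
rank_features <- function(fm, method = c("ttest", "mi", "chi2")) {
  method <- match.arg(method)
  m <- fm$matrix
  is_case <- fm$patients$group == "case"
  if (!any(is_case) || all(is_case)) stop("both groups must be non-empty")
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (method == "ttest") {
    x1 <- m[is_case, , drop = FALSE]
    x0 <- m[!is_case, , drop = FALSE]
    m1 <- Matrix::colMeans(x1); m0 <- Matrix::colMeans(x0)
    v1 <- (Matrix::colSums(x1^2) - n1 * m1^2) / max(n1 - 1, 1)
    v0 <- (Matrix::colSums(x0^2) - n0 * m0^2) / max(n0 - 1, 1)
    v1 <- pmax(v1, 0); v0 <- pmax(v0, 0)
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n0)
    d <- abs(m1 - m0)
    score <- ifelse(se2 > 0, d / sqrt(se2),
                    ifelse(d == 0, 0, .Machine$double.xmax))
    score <- pmin(score, .Machine$double.xmax)
  } else {
    a <- Matrix::colSums(m[is_case, , drop = FALSE] > 0)
    c_ <- Matrix::colSums(m[!is_case, , drop = FALSE] > 0)
    b <- n1 - a; d_ <- n0 - c_
    if (method == "mi") {
      score <- vapply(seq_along(a), function(j)
        mi_from_cells(a[j], b[j], c_[j], d_[j]), numeric(1))
    } else {
      n <- n1 + n0
      denom <- (a + b) * (c_ + d_) * (a + c_) * (b + d_)
      score <- ifelse(denom == 0, 0, n * (a * d_ - b * c_)^2 / denom)
    }
  }
  score <- unname(score)
  ord <- order(-score, fm$features$feature, method = "radix")
  scores <- data.frame(feature = fm$features$feature[ord],
                       event_type = fm$features$event_type[ord],
                       level = fm$features$level[ord],
                       score = score[ord],
                       stringsAsFactors = FALSE)
  scores$rank <- seq_len(nrow(scores))
  structure(list(scores = scores,
                 informative = scores$feature[scores$score > 0],
                 method = method),
            class = "ehr_ranking")
}

#' @exportS3Method print ehr_ranking
print.ehr_ranking <- function(x, ...) {
  cat(sprintf("<ehr_ranking> method=%s, %d features, %d informative\n",
              x$method, nrow(x$scores), length(x$informative)))
  print(utils::head(x$scores, 5))
  invisible(x)
}

#' Select the top fraction of informative features
#'
#' Returns the first `ceiling(percent/100 * n_informative)` features of
#' the informative set (score strictly above zero), in rank order;
#' `percent = 100` selects exactly the informative set.
#'
#' @param ranking an `ehr_ranking`.
#' @param percent selection percentage in (0, 100].
#' @return Character vector of feature identifiers (possibly empty, with
#'   a warning, when no feature is informative).
#' @export
select_top <- function(ranking, percent = 10) {
  stopifnot(inherits(ranking, "ehr_ranking"), percent > 0, percent <= 100)
  inf <- ranking$informative
  if (!length(inf)) {
    warning("no informative features (all scores zero)")
    return(character(0))
  }
  inf[seq_len(ceiling(percent / 100 * length(inf)))]
}

#' Export a ranking as CSV
#' @param ranking an `ehr_ranking`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_ranking <- function(ranking, path) {
  utils::write.csv(ranking$scores, path, row.names = FALSE)
  invisible(path)
}
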