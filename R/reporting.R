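#' Top-ranked feature table with group prevalences
#'
#' The human-readable report of the highest-scoring features: for each
#' feature, its event type and level, the percentage of cases and of
#' controls that carry it at least once, and its ranking score.
#' Features carried by fewer than `min_case_percent` percent of cases
#' are excluded.
#'
#' @param fm an `ehr_feature_matrix` over the cohort being reported
#'   (any encoding; presence is what matters).
#' @param ranking an `ehr_ranking` over the same feature universe.
#' @param k number of rows.
#' @param min_case_percent minimum case prevalence, in percent
#'   (default 5).
#' @return Data frame: `feature`, `event_type`, `level`, `pct_cases`,
#'   `pct_controls`, `score`.
#' @export
top_feature_table <- function(fm, ranking, k = 25, min_case_percent = 5) {
  stopifnot(inherits(fm, "ehr_feature_matrix"),
            inherits(ranking, "ehr_ranking"))
  is_case <- fm$patients$group == "case"
  pres <- fm$matrix > 0
  pct_case <- 100 * Matrix::colSums(pres[is_case, , drop = FALSE]) /
    sum(is_case)
  pct_ctrl <- 100 * Matrix::colSums(pres[!is_case, , drop = FALSE]) /
    sum(!is_case)
  sc <- ranking$scores
  m <- match(sc$feature, colnames(fm$matrix))
  sc$pct_cases <- pct_case[m]
  sc$pct_controls <- pct_ctrl[m]
  sc <- sc[!is.na(sc$pct_cases) & sc$pct_cases >= min_case_percent, ,
           drop = FALSE]
  out <- utils::head(sc, k)[, c("feature", "event_type", "level", "pct_cases",
                         "pct_controls", "score")]
  rownames(out) <- NULL
  out
}

#' Average-AUC series across a sweep
#'
#' Aggregates an [sweep_evaluation()] result into one series of
#' (cutoff, average AUC) per group, where the average is
#' [average_auc()] across the classifiers present.  With
#' `grouping = "classifier"` no averaging happens and each series is a
#' single classifier's AUC over time.  For other groupings, cells where
#' some classifier result is missing are omitted with a warning.
#'
#' @param results an `ehr_sweep` data frame (needs a `config` column for
#'   non-classifier groupings).
#' @param grouping `"classifier"` or `"config"`.
#' @return Data frame: `group`, `cutoff_days`, `avg_auc`, `n_classifiers`.
#' @export
auc_series <- function(results, grouping = c("config", "classifier")) {
  grouping <- match.arg(grouping)
  df <- as.data.frame(results)
  if (grouping == "classifier") {
    out <- df[, c("classifier", "cutoff_days", "auc")]
    names(out) <- c("group", "cutoff_days", "avg_auc")
    out$n_classifiers <- 1L
  } else {
    expected <- length(unique(df$classifier))
    agg <- aggregate(auc ~ config + cutoff_days, data = df,
                     FUN = function(x) c(avg = average_auc(x), n = length(x)))
    out <- data.frame(group = agg$config, cutoff_days = agg$cutoff_days,
                      avg_auc = agg$auc[, "avg"],
                      n_classifiers = as.integer(agg$auc[, "n"]))
    short <- out$n_classifiers < expected
    if (any(short)) {
      warning(sum(short), " point(s) omitted: missing classifier results")
      out <- out[!short, , drop = FALSE]
    }
  }
  out[order(out$group, out$cutoff_days), ]
}

#' Plot average-AUC series over time
#'
#' One line per group, horizon (days before diagnosis) on the x axis
#' reversed so that time flows toward diagnosis.
#'
#' @param series output of [auc_series()].
#' @param main plot title.
#' @return The series, invisibly.
#' @export
plot_auc_series <- function(series, main = "Average AUC over time") {
  groups <- unique(series$group)
  cuts <- sort(unique(series$cutoff_days))
  mat <- sapply(groups, function(g) {
    s <- series[series$group == g, ]
    s$avg_auc[match(cuts, s$cutoff_days)]
  })
  graphics::matplot(cuts, mat, type = "b", pch = seq_along(groups),
                    lty = 1, xlim = rev(range(cuts)),
                    xlab = "days before diagnosis", ylab = "average AUC",
                    main = main)
  graphics::legend("bottomleft", legend = groups, pch = seq_along(groups),
                   col = seq_along(groups), lty = 1, bty = "n")
  invisible(series)
}

#' Run manifest for reproducibility
#'
#' Every report row is traceable to a manifest: the configuration hash,
#' the seed, and the package version that produced it.
#'
#' @param config the [ehr_config()] (or any serializable configuration).
#' @param seed the top-level seed of the run.
#' @return A list with `config_hash` (md5 of the canonical JSON),
#'   `seed`, `package_version` and `created` (ISO timestamp).
#' @export
run_manifest <- function(config, seed) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  list(config_hash = unname(tools::md5sum(tf)),
       seed = seed,
       package_version = as.character(utils::packageVersion("ehrmine")),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write a manifest (plus optional results) as JSON
#' @param manifest output of [run_manifest()].
#' @param path output path.
#' @param results optional data frame of results to embed.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path, results = NULL) {
  if (!is.null(results)) manifest$results <- as.data.frame(results)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
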