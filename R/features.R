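#' Discretize a lab result against its reference range
#'
#' A lab value is represented by one of three outcome features: below the
#' reference range, within it, or above it.  Bounds are inclusive: a
#' value equal to either bound is `WITHIN`.
#'
#' @param test_id character vector of test identifiers.
#' @param value numeric vector of measured values.
#' @param ref_low,ref_high numeric vectors of reference bounds.
#' @return Character vector of features of the form `"Hb::ABOVE"`;
#'   `NA` (with a warning) where the bounds are missing.
#' @export
encode_lab <- function(test_id, value, ref_low, ref_high) {
  out <- rep(NA_character_, length(test_id))
  bad <- is.na(ref_low) | is.na(ref_high) | is.na(value) | is.na(test_id)
  if (any(bad))
    warning(sum(bad), " lab event(s) without reference bounds skipped")
  ok <- !bad
  cat3 <- ifelse(value[ok] < ref_low[ok], "BELOW",
                 ifelse(value[ok] > ref_high[ok], "ABOVE", "WITHIN"))
  out[ok] <- paste0(test_id[ok], "::", cat3)
  out
}

#' Representation configuration for the feature matrix
#'
#' @param text_levels subset of `1:4`; hierarchy levels used to roll up
#'   text entities.
#' @param icd_levels subset of `c("chapter","section","subsection","full")`.
#' @param atc_levels subset of `c("main","l3","l4","full")`.
#' @param include_types subset of the five event types to include.
#' @return A list of class `ehr_representation`.
#' @export
ehr_representation <- function(text_levels = 1:4,
                           icd_levels = c("chapter", "section",
                                          "subsection", "full"),
                           atc_levels = "full",
                           include_types = EVENT_TYPES) {
  stopifnot(all(text_levels %in% 1:4),
            all(icd_levels %in% c("chapter", "section", "subsection", "full")),
            all(atc_levels %in% c("main", "l3", "l4", "full")),
            all(include_types %in% EVENT_TYPES))
  structure(list(text_levels = sort(unique(text_levels)),
                 icd_levels = icd_levels, atc_levels = atc_levels,
                 include_types = include_types),
            class = "ehr_representation")
}

#' Build the patient-by-feature matrix
#'
#' Assembles the sparse matrix of event features per patient under a
#' chosen representation and encoding.  Text entities are rolled up
#' through the word-containment hierarchy at the selected levels, ICD and
#' ATC codes are expanded to their selected hierarchy levels, procedure
#' codes enter as-is, and lab results enter as three-way reference-range
#' outcomes.  Feature identifiers are type- and level-prefixed
#' (`"TEXT:L1:leukaemia"`, `"ICD:section:C51-C58"`, ...), so features of
#' different event types never collide.
#'
#' Encodings: `count` (raw occurrence counts), `binary` (did the patient
#' ever experience the event), `l2norm` (counts scaled to unit Euclidean
#' row norm) and `tfidf` (counts times `1 + log((N+1)/(df+1))`, `N` =
#' patients, `df` = patients with the feature).
#'
#' @param cohort a preprocessed [ehr_cohort()] (normalized, censored,
#'   rare-pruned).
#' @param rep_config an [ehr_representation()].
#' @param encoding one of `"count"`, `"binary"`, `"l2norm"`, `"tfidf"`.
#' @param hierarchy optionally a prebuilt `ehr_text_hierarchy`; by
#'   default one is built from the cohort's text vocabulary.
#' @return An object of class `ehr_feature_matrix`: `matrix` (a
#'   `dgCMatrix`, patients by features), `patients` (data frame with
#'   `patient_id`, `group`), `features` (data frame with `feature`,
#'   `event_type`, `level`), `encoding`.
#' @export
build_matrix <- function(cohort, rep_config = ehr_representation(),
                         encoding = c("count", "binary", "l2norm", "tfidf"),
                         hierarchy = NULL) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(rep_config, "ehr_representation"))
  ev <- cohort$events
  ev <- ev[ev$event_type %in% rep_config$include_types, , drop = FALSE]
  pat <- cohort$patients
  pieces <- list()

  if ("TEXT_ENTITY" %in% rep_config$include_types) {
    txt <- ev[ev$event_type == "TEXT_ENTITY", , drop = FALSE]
    if (nrow(txt)) {
      if (is.null(hierarchy))
        hierarchy <- build_text_hierarchy(unique(txt$surface))
      closures <- surface_closures(unique(txt$surface), hierarchy,
                                   rep_config$text_levels)
      lvl <- hierarchy$nodes$level[match(names(closures),
                                         hierarchy$nodes$surface)]
      cl_feats <- lapply(closures, function(cl) {
        m <- match(cl, hierarchy$nodes$surface)
        l <- ifelse(is.na(m), pmin(lengths(split_words(cl)), 4L),
                    hierarchy$nodes$level[m])
        paste0("TEXT:L", l, ":", cl)
      })
      kk <- lengths(cl_feats[txt$surface])
      pieces$text <- data.frame(
        patient_id = rep(txt$patient_id, kk),
        feature = unlist(cl_feats[txt$surface], use.names = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  if ("ICD" %in% rep_config$include_types) {
    icd <- ev[ev$event_type == "ICD", , drop = FALSE]
    if (nrow(icd)) {
      uniq <- unique(icd$surface)
      exp_of <- lapply(uniq, function(cd) {
        f <- suppressWarnings(expand_icd(cd, rep_config$icd_levels))
        if (length(f)) paste0("ICD:", names(f), ":", f) else character(0)
      })
      names(exp_of) <- uniq
      kk <- lengths(exp_of[icd$surface])
      pieces$icd <- data.frame(
        patient_id = rep(icd$patient_id, kk),
        feature = unlist(exp_of[icd$surface], use.names = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  if ("ATC" %in% rep_config$include_types) {
    atc <- ev[ev$event_type == "ATC", , drop = FALSE]
    if (nrow(atc)) {
      uniq <- unique(atc$surface)
      exp_of <- lapply(uniq, function(cd) {
        f <- expand_atc(cd, rep_config$atc_levels)
        paste0("ATC:", names(f), ":", f)
      })
      names(exp_of) <- uniq
      kk <- lengths(exp_of[atc$surface])
      pieces$atc <- data.frame(
        patient_id = rep(atc$patient_id, kk),
        feature = unlist(exp_of[atc$surface], use.names = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  if ("PROC" %in% rep_config$include_types) {
    prc <- ev[ev$event_type == "PROC", , drop = FALSE]
    if (nrow(prc))
      pieces$proc <- data.frame(patient_id = prc$patient_id,
                                feature = paste0("PROC:full:", prc$surface),
                                stringsAsFactors = FALSE)
  }
  if ("LAB" %in% rep_config$include_types) {
    lab <- ev[ev$event_type == "LAB", , drop = FALSE]
    if (nrow(lab)) {
      f <- encode_lab(lab$test_id, lab$value, lab$ref_low, lab$ref_high)
      ok <- !is.na(f)
      if (any(ok))
        pieces$lab <- data.frame(patient_id = lab$patient_id[ok],
                                 feature = paste0("LAB:cat:", f[ok]),
                                 stringsAsFactors = FALSE)
    }
  }

  trip <- do.call(rbind, unname(pieces))
  if (is.null(trip) || nrow(trip) == 0) {
    stop("empty feature universe; relax pruning or include more event types")
  } else {
    feats <- sort(unique(trip$feature))
    i <- match(trip$patient_id, pat$patient_id)
    j <- match(trip$feature, feats)
    mat <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                dims = c(nrow(pat), length(feats)))
  }
  dimnames(mat) <- list(pat$patient_id, feats)
  features <- data.frame(feature = feats,
                         event_type = sub("^([^:]+):.*$", "\\1", feats),
                         level = sub("^[^:]+:([^:]+):.*$", "\\1", feats),
                         stringsAsFactors = FALSE)
  fm <- structure(list(matrix = mat,
                       patients = pat[, c("patient_id", "group")],
                       features = features,
                       encoding = "count",
                       rep_config = rep_config),
                  class = "ehr_feature_matrix")
  set_encoding(fm, encoding)
}

#' Re-encode a feature matrix
#'
#' Transforms a count-encoded matrix into any of the supported encodings
#' without rebuilding it; the sparsity pattern is unchanged.
#'
#' @param fm an `ehr_feature_matrix` with `count` encoding.
#' @param encoding target encoding.
#' @return The re-encoded `ehr_feature_matrix`.
#' @export
set_encoding <- function(fm, encoding = c("count", "binary", "l2norm", "tfidf")) {
  encoding <- match.arg(encoding)
  if (fm$encoding != "count")
    stop("re-encoding starts from a count matrix")
  m <- fm$matrix
  if (encoding == "binary") {
    m@x <- rep(1, length(m@x))
  } else if (encoding == "l2norm") {
    nrm <- sqrt(Matrix::rowSums(m^2))
    nrm[nrm == 0] <- 1
    m <- Matrix::Diagonal(x = 1 / nrm) %*% m
    dimnames(m) <- dimnames(fm$matrix)
  } else if (encoding == "tfidf") {
    n <- nrow(m)
    df <- Matrix::colSums(m > 0)
    w <- 1 + log((n + 1) / (df + 1))
    m <- m %*% Matrix::Diagonal(x = w)
    dimnames(m) <- dimnames(fm$matrix)
  }
  fm$matrix <- methods::as(m, "CsparseMatrix")
  fm$encoding <- encoding
  fm
}

#' @exportS3Method print ehr_feature_matrix
print.ehr_feature_matrix <- function(x, ...) {
  cat(sprintf("<ehr_feature_matrix> %d patients x %d features (%s encoding, %.2f%% filled)\n",
              nrow(x$matrix), ncol(x$matrix), x$encoding,
              if (length(x$matrix)) 100 * Matrix::nnzero(x$matrix) /
                length(x$matrix) else 0))
  invisible(x)
}

#' Restrict a feature matrix to a set of features
#' @param fm an `ehr_feature_matrix`.
#' @param features character vector of feature identifiers; features not
#'   present in the matrix are ignored.
#' @return The restricted `ehr_feature_matrix`.
#' @export
restrict_features <- function(fm, features) {
  keep <- fm$features$feature %in% features
  fm$matrix <- fm$matrix[, keep, drop = FALSE]
  fm$features <- fm$features[keep, , drop = FALSE]
  fm
}

#' Export a feature matrix as MatrixMarket plus CSV sidecars
#' @param fm an `ehr_feature_matrix`.
#' @param stem path stem; writes `<stem>.mtx`, `<stem>-rows.csv`,
#'   `<stem>-cols.csv`.
#' @return The stem, invisibly.
#' @export
export_matrix <- function(fm, stem) {
  Matrix::writeMM(fm$matrix, paste0(stem, ".mtx"))
  utils::write.csv(fm$patients, paste0(stem, "-rows.csv"), row.names = FALSE)
  utils::write.csv(fm$features, paste0(stem, "-cols.csv"), row.names = FALSE)
  invisible(stem)
}
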