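#' Levenshtein edit distance
#'
#' Standard unit-cost edit distance (insertions, deletions,
#' substitutions), computed elementwise over recycled character vectors.
#'
#' @param a,b character vectors, recycled to a common length.
#' @return Integer vector of distances.
#' @export
#' @examples
#' levenshtein("thyreoideacancer", "tyreoideacancer")  # 1
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- integer(n)
  for (i in seq_len(n))
    out[i] <- adist(a[i], b[i], costs = 1L)[1, 1]
  out
}

split_words <- function(x) strsplit(x, " ", fixed = TRUE)

#' Can two surface forms share a spelling-group edge?
#'
#' The constrained linkage rule used for grouping spelling variants of
#' lemmatized clinical entities:
#'
#' * equal word count `n >= 2`: every aligned word pair is at distance at
#'   most 1, at most one pair is at distance exactly 1, and every aligned
#'   pair shares its first letter;
#' * both single words: whole-string distance at most 1 and the same
#'   first letter;
#' * differing word counts (a compound written with or without spaces):
#'   whole-string distance at most 1 and the same first letter of the
#'   full string.
#'
#' First-letter agreement is required because edits at the start of a
#' word usually change the concept, not the spelling.
#'
#' @param a,b character vectors of surfaces (lower-case, single-space
#'   separated), recycled elementwise.
#' @return Logical vector.
#' @export
linkable <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  wa <- split_words(a)
  wb <- split_words(b)
  out <- logical(n)
  for (i in seq_len(n)) {
    x <- wa[[i]]; y <- wb[[i]]
    if (length(x) == length(y) && length(x) >= 2) {
      if (!all(substr(x, 1, 1) == substr(y, 1, 1))) next
      d <- levenshtein(x, y)
      out[i] <- all(d <= 1) && sum(d == 1) <= 1
    } else {
      out[i] <- substr(a[i], 1, 1) == substr(b[i], 1, 1) &&
        levenshtein(a[i], b[i]) <= 1
    }
  }
  out
}

#' Tabulate the text-entity vocabulary of a cohort
#'
#' Counts corpus occurrences of each distinct text-entity surface.  A
#' `"NEG::"` negation marker, if present, is transparent: marked and
#' unmarked mentions count toward the same underlying surface, so that
#' spelling normalization treats them alike.
#'
#' @param cohort an [ehr_cohort()].
#' @return Named integer vector (surface -> occurrence count).
#' @export
surface_vocabulary <- function(cohort) {
  s <- cohort$events$surface[cohort$events$event_type == "TEXT_ENTITY"]
  s <- strip_neg(s)
  tab <- table(s)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

strip_neg <- function(s) {
  marked <- startsWith(s, NEG_MARKER)
  s[marked] <- substring(s[marked], nchar(NEG_MARKER) + 1)
  s
}

#' Group spelling variants and pick canonical forms
#'
#' Builds the graph over the vocabulary whose edges are [linkable()]
#' pairs and takes its connected components as spelling groups, so that a
#' surface joins a group when it is within one constrained edit of *some*
#' member (chain linkage).  Every member of a group is mapped to the
#' group's most frequent surface; frequency ties break to the
#' lexicographically smallest surface.
#'
#' Candidate edges are restricted to surfaces sharing their first letter
#' and within one character of each other in total length -- both are
#' necessary conditions for linkability, so the restriction is exact.
#'
#' @param vocab named integer vector of corpus frequencies, as returned
#'   by [surface_vocabulary()].
#' @return An object of class `ehr_normalization_map` with elements
#'   `canonical` (named character: surface -> canonical surface) and
#'   `groups` (list of character vectors partitioning the vocabulary).
#' @export
build_groups <- function(vocab) {
  stopifnot(is.numeric(vocab), !is.null(names(vocab)))
  surfaces <- names(vocab)
  n <- length(surfaces)
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    first <- substr(surfaces, 1, 1)
    len <- nchar(surfaces)
    blocks <- split(seq_len(n), first)
    pair_list <- list()
    for (blk in blocks) {
      if (length(blk) < 2) next
      o <- blk[order(len[blk])]
      lo <- len[o]
      # sorted-by-length sweep: only pairs within +-1 total length
      cand_i <- integer(0); cand_j <- integer(0)
      start <- 1
      for (k in 2:length(o)) {
        while (lo[k] - lo[start] > 1) start <- start + 1
        if (k > start) {
          cand_i <- c(cand_i, o[start:(k - 1)])
          cand_j <- c(cand_j, rep(o[k], k - start))
        }
      }
      if (length(cand_i)) {
        ok <- linkable(surfaces[cand_i], surfaces[cand_j])
        if (any(ok))
          pair_list[[length(pair_list) + 1]] <- cbind(cand_i[ok], cand_j[ok])
      }
    }
    if (length(pair_list)) edges <- do.call(rbind, pair_list)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  groups <- split(surfaces, comp)
  canonical_of_group <- vapply(groups, function(members) {
    f <- vocab[members]
    best <- members[f == max(f)]
    sort(best)[1]
  }, character(1))
  canonical <- canonical_of_group[match(comp, as.integer(names(groups)))]
  names(canonical) <- surfaces
  names(groups) <- canonical_of_group
  structure(list(canonical = canonical, groups = unname(groups),
                 vocab = vocab),
            class = "ehr_normalization_map")
}

#' @exportS3Method print ehr_normalization_map
print.ehr_normalization_map <- function(x, ...) {
  sizes <- lengths(x$groups)
  cat(sprintf("<ehr_normalization_map> %d surfaces -> %d groups (largest %d)\n",
              length(x$canonical), length(x$groups),
              if (length(sizes)) max(sizes) else 0))
  invisible(x)
}

#' Replace surfaces by their canonical spelling
#'
#' Rewrites every text-entity surface in the cohort to the canonical form
#' of its spelling group.  Surfaces outside the map's vocabulary pass
#' through unchanged, non-text events are untouched, and the operation is
#' idempotent (canonical forms map to themselves).  The `"NEG::"`
#' negation marker is preserved around the rewritten surface.
#'
#' @param cohort an [ehr_cohort()].
#' @param map an `ehr_normalization_map` from [build_groups()].
#' @return The normalized [ehr_cohort()].
#' @export
apply_normalization <- function(cohort, map) {
  stopifnot(inherits(map, "ehr_normalization_map"))
  ev <- cohort$events
  i <- which(ev$event_type == "TEXT_ENTITY")
  if (!length(i)) return(cohort)
  s <- ev$surface[i]
  marked <- startsWith(s, NEG_MARKER)
  bare <- strip_neg(s)
  canon <- map$canonical[bare]
  canon[is.na(canon)] <- bare[is.na(canon)]
  ev$surface[i] <- ifelse(marked, paste0(NEG_MARKER, canon), canon)
  replace_events(cohort, ev)
}

#' Export a normalization map as CSV
#' @param map an `ehr_normalization_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_normalization_map <- function(map, path) {
  utils::write.csv(data.frame(surface = names(map$canonical),
                              canonical = unname(map$canonical)),
                   path, row.names = FALSE)
  invisible(path)
}
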