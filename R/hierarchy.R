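#' Word-containment hierarchy over textual events
#'
#' Builds the DAG that organizes canonical text-entity surfaces by word
#' containment: a surface `p` is an ancestor of `c` whenever the word set
#' of `p` is a strict subset of the word set of `c` (order- and
#' multiplicity-insensitive).  Nodes live on levels given by word count,
#' capped at 4 ("four or more words" all sit on the fourth level); a node
#' may have several parents (an "infected wound" descends from both
#' "wound" and "infected").  The ancestor index is transitively closed by
#' construction, which is exactly what level-wise feature rollup needs.
#'
#' @param vocab character vector of canonical (post-normalization)
#'   surfaces.
#' @return An object of class `ehr_text_hierarchy` with `nodes` (data
#'   frame: `surface`, `level`, `n_words`) and `ancestors` (named list:
#'   surface -> character vector of ancestor surfaces).
#' @export
#' @examples
#' h <- build_text_hierarchy(c("wound", "infected", "infected wound"))
#' h$ancestors[["infected wound"]]
build_text_hierarchy <- function(vocab) {
  vocab <- unique(as.character(vocab))
  words <- lapply(split_words(vocab), unique)
  nw <- lengths(split_words(vocab))
  level <- pmin(nw, 4L)
  # hash word-set key -> node indices sharing that exact word set
  key_of <- vapply(words, function(w) paste(sort(w), collapse = "\r"),
                   character(1))
  by_key <- split(seq_along(vocab), key_of)
  ancestors <- vector("list", length(vocab))
  names(ancestors) <- vocab
  for (i in seq_along(vocab)) {
    w <- words[[i]]
    k <- length(w)
    if (k == 1) { ancestors[[i]] <- character(0); next }
    # enumerate proper non-empty subsets of the word set and look each up
    anc <- integer(0)
    for (m in seq_len(k - 1)) {
      combs <- utils::combn(sort(w), m, simplify = FALSE)
      for (sub in combs) {
        hitkey <- paste(sub, collapse = "\r")
        hit <- by_key[[hitkey]]
        if (!is.null(hit)) anc <- c(anc, hit)
      }
    }
    ancestors[[i]] <- vocab[sort(unique(anc))]
  }
  structure(list(
    nodes = data.frame(surface = vocab, level = level, n_words = nw,
                       stringsAsFactors = FALSE),
    ancestors = ancestors), class = "ehr_text_hierarchy")
}

#' @exportS3Method print ehr_text_hierarchy
print.ehr_text_hierarchy <- function(x, ...) {
  tab <- table(factor(x$nodes$level, levels = 1:4))
  cat(sprintf("<ehr_text_hierarchy> %d nodes (levels 1-4: %s), %d containment pairs\n",
              nrow(x$nodes), paste(tab, collapse = "/"),
              sum(lengths(x$ancestors))))
  invisible(x)
}

#' Export the containment relation as an edge list
#'
#' One row per (ancestor, descendant) containment pair with their levels.
#' The export is the transitive closure, not only adjacent-level edges:
#' for rollup the two are equivalent, and the closure is what the package
#' stores.
#'
#' @param hierarchy an `ehr_text_hierarchy`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_hierarchy_edges <- function(hierarchy, path) {
  nodes <- hierarchy$nodes
  child <- rep(nodes$surface, lengths(hierarchy$ancestors))
  parent <- unlist(hierarchy$ancestors, use.names = FALSE)
  df <- data.frame(parent = parent, child = child,
                   parent_level = nodes$level[match(parent, nodes$surface)],
                   child_level = nodes$level[match(child, nodes$surface)])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Roll text occurrences up the containment hierarchy
#'
#' Each text-entity occurrence contributes one count to itself and to
#' every ancestor whose level is among `levels`; a long, specific mention
#' such as "chronic myeloid leukaemia" is thereby also represented by the
#' short, general "leukaemia" when level 1 is selected.  A surface absent
#' from the hierarchy contributes only to itself, and only when its own
#' level (word count capped at 4) is selected.
#'
#' @param surfaces character vector of normalized text-entity
#'   occurrences (one element per occurrence, repeats allowed).
#' @param hierarchy an `ehr_text_hierarchy`.
#' @param levels non-empty subset of `1:4`.
#' @return Data frame `feature` (node surface), `level`, `count` -- the
#'   rolled-up multiset of features.
#' @export
text_features <- function(surfaces, hierarchy, levels = 1:4) {
  stopifnot(length(levels) > 0, all(levels %in% 1:4))
  closure <- surface_closures(unique(surfaces), hierarchy, levels)
  occ <- table(surfaces)
  feat <- unlist(closure[names(occ)], use.names = FALSE)
  count <- rep(as.integer(occ), lengths(closure[names(occ)]))
  if (!length(feat))
    return(data.frame(feature = character(0), level = integer(0),
                      count = integer(0)))
  agg <- rowsum(count, feat)
  lvl_of <- function(s) {
    m <- match(s, hierarchy$nodes$surface)
    ifelse(is.na(m), pmin(lengths(split_words(s)), 4L),
           hierarchy$nodes$level[m])
  }
  data.frame(feature = rownames(agg),
             level = as.integer(lvl_of(rownames(agg))),
             count = as.integer(agg[, 1]),
             stringsAsFactors = FALSE)
}

# For each unique surface: the node surfaces (self + ancestors) at the
# selected levels that one occurrence of it contributes to.
surface_closures <- function(uniq, hierarchy, levels) {
  nodes <- hierarchy$nodes
  m <- match(uniq, nodes$surface)
  out <- vector("list", length(uniq))
  names(out) <- uniq
  own_level <- pmin(lengths(split_words(uniq)), 4L)
  for (i in seq_along(uniq)) {
    if (is.na(m[i])) {
      out[[i]] <- if (own_level[i] %in% levels) uniq[i] else character(0)
    } else {
      cl <- c(uniq[i], hierarchy$ancestors[[m[i]]])
      lv <- nodes$level[match(cl, nodes$surface)]
      out[[i]] <- cl[lv %in% levels]
    }
  }
  out
}

## ---- ICD-10 ranges ---------------------------------------------------

# Chapter ranges of ICD-10 (letter + two digits, inclusive).
icd_chapters <- function() {
  data.frame(
    lo = c("A00", "C00", "D50", "E00", "F00", "G00", "H00", "H60", "I00",
           "J00", "K00", "L00", "M00", "N00", "O00", "P00", "Q00", "R00",
           "S00", "U00", "V01", "Z00"),
    hi = c("B99", "D48", "D89", "E90", "F99", "G99", "H59", "H95", "I99",
           "J99", "K93", "L99", "M99", "N99", "O99", "P96", "Q99", "R99",
           "T98", "U99", "Y98", "Z99"),
    stringsAsFactors = FALSE)
}

# An embedded subset of ICD-10 section ranges covering the code points the
# synthetic generator emits plus the gynaecological-oncology neighbourhood;
# the full classification is deliberately not bundled, and codes outside
# these sections simply skip the section level.
icd_sections <- function() {
  data.frame(
    lo = c("A00", "B15", "C00", "C15", "C30", "C40", "C43", "C45", "C50",
           "C51", "C60", "C64", "C69", "C73", "C76", "C81", "C97", "D00",
           "D10", "D37", "D50", "E00", "E10", "E65", "F30", "F40", "G40",
           "H10", "I10", "I20", "I30", "J00", "J09", "J40", "K20", "K50",
           "K80", "L20", "L50", "M15", "M50", "M70", "N10", "N30", "N70",
           "N80", "N99", "O00", "O20", "P05", "Q50", "R00", "R10", "R30",
           "R50", "S30", "T80", "U00", "V01", "Z00", "Z30", "Z40", "Z80"),
    hi = c("A09", "B19", "C14", "C26", "C39", "C41", "C44", "C49", "C50",
           "C58", "C63", "C68", "C72", "C75", "C80", "C96", "C97", "D09",
           "D36", "D48", "D53", "E07", "E14", "E68", "F39", "F48", "G47",
           "H13", "I15", "I25", "I52", "J06", "J18", "J47", "K31", "K52",
           "K87", "L30", "L54", "M19", "M54", "M79", "N16", "N39", "N77",
           "N98", "N99", "O08", "O29", "P08", "Q56", "R09", "R19", "R39",
           "R69", "S39", "T88", "U99", "Y98", "Z13", "Z39", "Z54", "Z99"),
    stringsAsFactors = FALSE)
}

icd_key <- function(root) {
  (match(substr(root, 1, 1), LETTERS) - 1L) * 100L +
    as.integer(substr(root, 2, 3))
}

range_label <- function(root, ranges) {
  k <- icd_key(root)
  hit <- which(icd_key(ranges$lo) <= k & k <= icd_key(ranges$hi))
  if (!length(hit)) return(NA_character_)
  r <- ranges[hit[1], ]
  if (r$lo == r$hi) r$lo else paste0(r$lo, "-", r$hi)
}

#' Expand an ICD-10 code to its hierarchy levels
#'
#' Emits one feature label per selected level: `chapter` is the chapter
#' range containing the three-character root (e.g. `"C00-D48"`),
#' `section` the section range (e.g. `"C51-C58"`), `subsection` the
#' three-character root itself and `full` the code as given.  Levels
#' whose range lookup fails are skipped; a code not matching the
#' letter-digit-digit shape triggers a warning and is emitted at the
#' `full` level only.
#'
#' @param code an ICD-10 code such as `"C530"` or `"C53.0"` (a dot after
#'   the root is tolerated and stripped).
#' @param levels subset of `c("chapter", "section", "subsection",
#'   "full")`.
#' @return Character vector of feature labels, named by level.
#' @export
#' @examples
#' expand_icd("C530")  # C00-D48, C51-C58, C53, C530
expand_icd <- function(code,
                       levels = c("chapter", "section", "subsection", "full")) {
  levels <- match.arg(levels, several.ok = TRUE)
  code <- sub(".", "", as.character(code), fixed = TRUE)
  if (!grepl("^[A-Z][0-9]{2}", code)) {
    warning("malformed ICD code '", code, "'; emitted at full level only")
    return(if ("full" %in% levels) c(full = code) else character(0))
  }
  root <- substr(code, 1, 3)
  out <- character(0)
  if ("chapter" %in% levels) {
    lab <- range_label(root, icd_chapters())
    if (!is.na(lab)) out <- c(out, chapter = lab)
  }
  if ("section" %in% levels) {
    lab <- range_label(root, icd_sections())
    if (!is.na(lab)) out <- c(out, section = lab)
  }
  if ("subsection" %in% levels) out <- c(out, subsection = root)
  if ("full" %in% levels) out <- c(out, full = code)
  out
}

#' Expand an ATC code to its hierarchy levels
#'
#' Prefix-derived levels of the Anatomical Therapeutic Chemical
#' classification: `main` is the anatomical main group (1 character),
#' `l3` the therapeutic/pharmacological subgroup (4 characters), `l4`
#' the chemical subgroup (5 characters) and `full` the complete code (up
#' to 7 characters).  Levels longer than the code are skipped.
#'
#' @param code an ATC code of 1--7 characters.
#' @param levels subset of `c("main", "l3", "l4", "full")`.
#' @return Character vector of feature labels, named by level.
#' @export
#' @examples
#' expand_atc("N02BE01")  # N, N02B, N02BE, N02BE01
expand_atc <- function(code, levels = c("main", "l3", "l4", "full")) {
  levels <- match.arg(levels, several.ok = TRUE)
  code <- as.character(code)
  if (is.na(code) || !nzchar(code)) stop("empty ATC code")
  nc <- nchar(code)
  out <- character(0)
  if ("main" %in% levels) out <- c(out, main = substr(code, 1, 1))
  if ("l3" %in% levels && nc >= 4) out <- c(out, l3 = substr(code, 1, 4))
  if ("l4" %in% levels && nc >= 5) out <- c(out, l4 = substr(code, 1, 5))
  if ("full" %in% levels) out <- c(out, full = code)
  out
}
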