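# Independent oracles used to verify the package implementations.
# These deliberately re-implement the definitions from scratch (different
# algorithms, different code paths) so that agreement is evidence, not
# tautology.

# Plain recursive Levenshtein straight from the definition; exponential,
# only usable on very short strings.
rlev <- function(a, b) {
  if (!nchar(a)) return(nchar(b))
  if (!nchar(b)) return(nchar(a))
  ta <- substr(a, 2, nchar(a))
  tb <- substr(b, 2, nchar(b))
  sub_cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  min(rlev(ta, b) + 1L, rlev(a, tb) + 1L, rlev(ta, tb) + sub_cost)
}

# Vectorised Wagner-Fischer dynamic programme over many pairs at once:
# pairs are grouped by the two string lengths and the DP table is carried
# as one vector per cell across all pairs in the group.
vec_lev <- function(a, b) {
  stopifnot(length(a) == length(b))
  out <- integer(length(a))
  na <- nchar(a); nb <- nchar(b)
  for (key in unique(paste(na, nb))) {
    idx <- which(paste(na, nb) == key)
    m <- na[idx[1]]; n <- nb[idx[1]]
    if (m == 0) { out[idx] <- n; next }
    if (n == 0) { out[idx] <- m; next }
    A <- matrix(unlist(strsplit(a[idx], "")), nrow = length(idx),
                byrow = TRUE)
    B <- matrix(unlist(strsplit(b[idx], "")), nrow = length(idx),
                byrow = TRUE)
    prev <- matrix(rep(0:n, each = length(idx)), nrow = length(idx))
    for (i in seq_len(m)) {
      cur <- matrix(0L, nrow = length(idx), ncol = n + 1)
      cur[, 1] <- i
      for (j in seq_len(n)) {
        cur[, j + 1] <- pmin(prev[, j + 1] + 1L,
                             cur[, j] + 1L,
                             prev[, j] + (A[, i] != B[, j]))
      }
      prev <- cur
    }
    out[idx] <- prev[, n + 1]
  }
  out
}

# Brute-force re-implementation of the constrained linkage rule.
oracle_linkable <- function(a, b) {
  wa <- strsplit(a, " ", fixed = TRUE)[[1]]
  wb <- strsplit(b, " ", fixed = TRUE)[[1]]
  if (length(wa) == length(wb) && length(wa) >= 2) {
    d <- mapply(function(x, y) vec_lev(x, y), wa, wb)
    first_ok <- all(substr(wa, 1, 1) == substr(wb, 1, 1))
    return(first_ok && all(d <= 1) && sum(d == 1) <= 1)
  }
  substr(a, 1, 1) == substr(b, 1, 1) && vec_lev(a, b) <= 1
}

# Union-find over all O(n^2) linkable pairs; returns group membership ids.
oracle_groups <- function(surfaces) {
  n <- length(surfaces)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (oracle_linkable(surfaces[i], surfaces[j])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# All strict word-set containment pairs, the slow way.
oracle_containment_pairs <- function(vocab) {
  ws <- lapply(strsplit(vocab, " ", fixed = TRUE), unique)
  cnt <- 0L
  n <- length(vocab)
  if (n < 2) return(0L)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && all(ws[[i]] %in% ws[[j]]) &&
        !setequal(ws[[i]], ws[[j]]))
      cnt <- cnt + 1L
  }
  cnt
}

# Exact central binomial interval [qbinom(a/2), qbinom(1 - a/2)].
binom_interval <- function(n, p, alpha = 0.01) {
  c(qbinom(alpha / 2, n, p), qbinom(1 - alpha / 2, n, p))
}

# Random lowercase strings for property tests.
random_strings <- function(n, min_len = 1, max_len = 8,
                           alphabet = letters[1:6]) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, sample(min_len:max_len, 1), replace = TRUE),
          collapse = ""), character(1))
}
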