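# Independent oracles used to cross-check the package implementation.

# Plain-R reference implementation of the global alignment score under the
# asymmetric affine gap scheme. Deliberately naive (full matrices, explicit
# loops); only used on short sequences.
r_align_score <- function(a, b, sch) {
  n <- nchar(a); m <- nchar(b)
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  NEG <- -1e30
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  qg <- function(j) {           # gap in query row (class by j residues used)
    if (j == 0) c(sch$query_left_open, sch$query_left_extend)
    else if (j == m) c(sch$query_right_open, sch$query_right_extend)
    else c(sch$query_internal_open, sch$query_internal_extend)
  }
  tg <- function(i) {           # gap in target row (class by i residues used)
    if (i == 0) c(sch$target_left_open, sch$target_left_extend)
    else if (i == n) c(sch$target_right_open, sch$target_right_extend)
    else c(sch$target_internal_open, sch$target_internal_extend)
  }
  for (j in seq_len(m)) {
    g <- tg(0)
    Y[1, j + 1] <- if (j == 1) g[1] else Y[1, j] + g[2]
  }
  for (i in seq_len(n)) {
    g <- qg(0)
    X[i + 1, 1] <- if (i == 1) g[1] else X[i, 1] + g[2]
    for (j in seq_len(m)) {
      s <- if (ac[i] == bc[j] && ac[i] != "N") sch$match else sch$mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      g <- qg(j)
      X[i + 1, j + 1] <- max(M[i, j + 1] + g[1], Y[i, j + 1] + g[1],
                             X[i, j + 1] + g[2])
      g <- tg(i)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + g[1], X[i + 1, j] + g[1],
                             Y[i + 1, j] + g[2])
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Brute-force TSD oracle: enumerate every (length, right-offset) pair with
# the left copy pinned to the element 5' boundary; longest first, then
# fewest mismatches, then leftmost right copy.
brute_tsd <- function(seq, s, e, min_len = 6, max_len = 25,
                      max_mismatch = 1, slack = 5) {
  n <- nchar(seq)
  hamm <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  best <- NULL
  for (L in max_len:min_len) {
    if (s - L < 0) next
    left <- substr(seq, s - L + 1, s)
    for (d in 0:slack) {
      if (e + d + L > n) next
      right <- substr(seq, e + d + 1, e + d + L)
      mm <- hamm(left, right)
      if (mm <= max_mismatch) {
        cand <- list(L = L, d = d, mm = mm, sequence = left)
        if (is.null(best) ||
            cand$L > best$L ||
            (cand$L == best$L && cand$mm < best$mm) ||
            (cand$L == best$L && cand$mm == best$mm && cand$d < best$d))
          best <- cand
      }
    }
    if (!is.null(best)) return(best)  # longest-first: stop at first length
  }
  best
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Printed per-category counts of the comparative study's summary tables,
# used as fixed inputs for the table-arithmetic checks.
published_counts <- function() {
  data.frame(
    category = c("CM", "CO", "CS", "MO", "MS", "OS",
                 "CMO", "CMS", "COS", "MOS"),
    total_candidates = c(170, 92, 517, 306, 244, 196, 345, 381, 467, 255),
    duplicates = c(38, 19, 106, 83, 42, 31, 153, 143, 181, 96),
    post_shared = c(43, 22, 267, 108, 61, 50, 20, 52, 63, 23),
    post_np = c(45, 22, 44, 77, 99, 81, 3, 5, 2, 4),
    post_other = c(44, 29, 100, 38, 42, 34, 169, 181, 221, 132),
    stringsAsFactors = FALSE)
}
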