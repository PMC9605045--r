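## ---------------------------------------------------------------------------
## Automated post-alignment inspection: TSD detection, near-parallel
## insertion calls, N-run / truncation / present-in-all failure classes,
## subfamily assignment and precise-parallel flagging.
## ---------------------------------------------------------------------------

## Estimate the 3' end of the poly-A tail downstream of `from` (0-based,
## exclusive): the first maximizer of the running score #A - 3 * #non-A.
## The penalty makes the score peak exactly at the tail terminus even with
## scattered substitutions inside the tail (a substitution near the very
## end truncates the estimate by at most a few bases, well inside the TSD
## search slack), while any downstream sequence of ordinary base
## composition - including an A-rich TSD copy - drives the score down and
## is never swallowed.
estimate_a_tail_end <- function(seq, from, max_tail = 60, non_a_penalty = 3) {
  n <- nchar(seq)
  hi <- min(n, from + max_tail)
  if (hi <= from) return(from)
  chars <- strsplit(substr(seq, from + 1, hi), "", fixed = TRUE)[[1]]
  score <- cumsum(ifelse(chars == "A", 1, -non_a_penalty))
  if (max(score) <= 0) return(from)
  from + which.max(score)
}

.hamming <- function(x, y) {
  sum(strsplit(x, "", fixed = TRUE)[[1]] !=
        strsplit(y, "", fixed = TRUE)[[1]])
}

#' Detect the target site duplication flanking an insertion
#'
#' Searches for the longest duplicated word (allowing up to `max_mismatch`
#' substitutions) whose left copy ends exactly at the element's 5'
#' boundary and whose right copy begins within a small slack window after
#' the A-tail. Preference order: longest first, then fewest mismatches,
#' then leftmost right-copy position.
#'
#' @param carrier_seq Unaligned carrier sequence.
#' @param alu_span 0-based half-open `(start, end)` of the element
#'   including the A-tail terminus estimate.
#' @param min_len,max_len TSD length bounds (defaults 6/25).
#' @param max_mismatch Maximum substitutions between the two copies
#'   (default 1).
#' @param slack Right-copy search window after the element end in bp
#'   (default 5).
#' @return A list of class `tsd_call` with `left_start`, `left_end`,
#'   `right_start`, `right_end` (0-based half-open), `sequence` (left
#'   copy) and `mismatches`; or `NULL` when no duplication is found.
#' @export
detect_tsd <- function(carrier_seq, alu_span, min_len = 6, max_len = 25,
                       max_mismatch = 1, slack = 5) {
  s <- alu_span[1]; e <- alu_span[2]
  n <- nchar(carrier_seq)
  stopifnot(s >= 0, e >= s, e <= n)
  for (L in seq(max_len, min_len)) {
    if (s - L < 0) next
    left <- substr(carrier_seq, s - L + 1, s)
    best <- NULL
    for (d in 0:slack) {
      if (e + d + L > n) break
      right <- substr(carrier_seq, e + d + 1, e + d + L)
      mm <- .hamming(left, right)
      if (mm <= max_mismatch && (is.null(best) || mm < best$mm)) {
        best <- list(d = d, mm = mm, right = right)
        if (mm == 0) break
      }
    }
    if (!is.null(best)) {
      return(structure(list(
        left_start = s - L, left_end = s,
        right_start = e + best$d, right_end = e + best$d + L,
        sequence = left, mismatches = best$mm), class = "tsd_call"))
    }
  }
  NULL
}

## Compatibility of two TSD calls: compare the common suffix (both left
## copies end at the element boundary, so suffix alignment is the shared
## anchor) and require at most `max_mismatch` substitutions.
tsds_compatible <- function(t1, t2, max_mismatch = 1) {
  if (is.null(t1) || is.null(t2)) return(FALSE)
  m <- min(nchar(t1$sequence), nchar(t2$sequence))
  s1 <- substr(t1$sequence, nchar(t1$sequence) - m + 1, nchar(t1$sequence))
  s2 <- substr(t2$sequence, nchar(t2$sequence) - m + 1, nchar(t2$sequence))
  .hamming(s1, s2) <= max_mismatch
}

## Fraction of consensus k-mers found exactly in a sequence: the fragment
## detector behind the "present in all genomes" failure class.
.kmer_fragment_share <- function(seq, consensus, k = 20) {
  n <- nchar(consensus)
  if (n < k || !nzchar(seq)) return(0)
  starts <- seq_len(n - k + 1)
  kmers <- substring(consensus, starts, starts + k - 1)
  mean(vapply(kmers, function(km) grepl(km, seq, fixed = TRUE), logical(1)))
}

#' Assign an Alu subfamily by consensus-library scoring
#'
#' Aligns each library consensus (target side) against the element
#' sequence and reports the best-scoring member; ties are broken
#' alphabetically. Divergence is mismatches over aligned columns. When no
#' member reaches the presence threshold the element is `"unclassified"`.
#'
#' @param alu_seq Element sequence (may include the A-tail).
#' @param library Named character vector of consensus sequences.
#' @param scheme A [scoring_scheme()].
#' @param threshold_fraction Presence threshold as a fraction of the
#'   maximum score (default 0.5).
#' @return List with `subfamily` (name or `"unclassified"`) and
#'   `divergence_pct`.
#' @export
assign_subfamily <- function(alu_seq, library, scheme = scoring_scheme(),
                             threshold_fraction = 0.5) {
  stopifnot(length(library) > 0, !is.null(names(library)))
  nm <- sort(names(library))
  best <- NULL
  for (name in nm) {
    al <- align_pair(library[[name]], alu_seq, scheme, traceback = TRUE)
    if (is.null(best) || al$score > best$score)
      best <- list(name = name, score = al$score,
                   mism = al$mismatches, cols = al$aligned_cols,
                   max_score = scheme$match * nchar(library[[name]]))
  }
  if (best$score < threshold_fraction * best$max_score)
    return(list(subfamily = "unclassified", divergence_pct = NA_real_))
  list(subfamily = best$name,
       divergence_pct = 100 * best$mism / max(1L, best$cols))
}

## Default subfamily -> lineage map used by the precise-parallel flag.
## Subfamilies of the same lineage differ by so few diagnostic bases that
## discordance between carriers is plausibly just sequence decay; only
## cross-lineage discordance flags a candidate precise parallel insertion.
default_lineage_map <- function() {
  c(Sc = "Sc", Sc5 = "Sc", Sc8 = "Sc",
    Ta7 = "Ta7",
    Ta10 = "Ta10", Ta15 = "Ta15",
    Sx = "S_old", Sx1 = "S_old", Sx3 = "S_old", Sx4 = "S_old",
    Sq = "S_old", Sq2 = "S_old", Sq10 = "S_old", Sz = "S_old",
    Sz6 = "S_old", Sp = "S_old", Sg = "S_old", Sg4 = "S_old",
    Sg7 = "S_old")
}

.lineage_of <- function(subfamily, map = default_lineage_map()) {
  key <- sub("^Alu", "", subfamily)
  if (key %in% names(map)) unname(map[[key]]) else key
}

#' Flag a possible precise parallel insertion
#'
#' A shared call whose carriers belong to different subfamily lineages is
#' probably two independent insertions at the same position rather than a
#' single insertion identical by descent; same-lineage disagreement (for
#' instance two Ta15-derived calls) is attributed to sequence decay and
#' does not flag.
#'
#' @param outcome An `inspection_outcome` with verdict `"shared"` and at
#'   least two subfamily-classified carriers (or a character vector of
#'   carrier subfamily names).
#' @param lineage_map Named map from subfamily to lineage.
#' @return `TRUE`, `FALSE`, or `NA` when any carrier is unclassified
#'   (indeterminate).
#' @export
flag_precise_parallel <- function(outcome,
                                  lineage_map = default_lineage_map()) {
  subs <- if (inherits(outcome, "inspection_outcome")) {
    unlist(outcome$subfamily, use.names = FALSE)
  } else as.character(outcome)
  subs <- subs[!is.na(subs)]
  if (length(subs) < 2) return(NA)
  if (any(subs == "unclassified")) return(NA)
  lins <- vapply(subs, .lineage_of, character(1), map = lineage_map)
  length(unique(lins)) > 1
}

## column index (1-based) of the `pos`-th residue (0-based) of a gapped row
.row_pos_to_col <- function(gapped_row, pos) {
  chars <- strsplit(gapped_row, "", fixed = TRUE)[[1]]
  npos <- which(chars != "-")
  if (pos + 1 > length(npos)) return(NA_integer_)
  npos[pos + 1]
}

#' Automated inspection of a categorized four-way alignment
#'
#' Operationalizes visual alignment inspection. In precedence order:
#' \enumerate{
#'   \item any row with an N fraction at or above `n_fraction_threshold`
#'     fails as `other/has_N`;
#'   \item any expected genome missing from the alignment, or any row
#'     shorter than 80% of its expected flank(+element) length, fails as
#'     `other/truncated`;
#'   \item consensus fragments detected (by exact k-mer content) in a
#'     nominally absent row fail as `other/present_in_all`;
#'   \item carriers whose insertion start columns differ by more than
#'     `np_offset_threshold`, or whose TSDs are incompatible, are called
#'     `near_parallel`;
#'   \item carriers agreeing in position with mutually compatible TSDs are
#'     validated as `shared`. A carrier with no detectable TSD cannot be
#'     validated and the locus falls back to `other/truncated`
#'     (undetermined status).
#' }
#'
#' @param alignment A `four_way_alignment`.
#' @param pattern Named logical presence vector over the four ingroup
#'   genomes (from presence scoring).
#' @param consensus Consensus sequence used for presence scoring.
#' @param scheme A [scoring_scheme()].
#' @param np_offset_threshold Column offset beyond which two carrier
#'   insertions are near-parallel (default 10).
#' @param n_fraction_threshold Row N fraction triggering `has_N`
#'   (default 0.05).
#' @param library Optional subfamily library; when given, carriers are
#'   subfamily-classified and the precise-parallel flag is computed.
#' @param presence Optional named list of precomputed
#'   [score_alu_presence()] results per row (avoids re-alignment).
#' @param flank Flank length used upstream (default 600).
#' @param nominal_insert Nominal element+tail length used in the
#'   truncation expectation (default 300).
#' @param tsd_max_mismatch Maximum mismatches for TSD compatibility
#'   (default 1).
#' @param fragment_share Minimum consensus k-mer share that counts as
#'   retained fragments (default 0.10).
#' @return Object of class `inspection_outcome`: list with `verdict`
#'   (`"shared"`/`"near_parallel"`/`"other"`), `other_reason` (`"has_N"`,
#'   `"truncated"`, `"present_in_all"` or `"none"`), `positions`
#'   (insertion start column per carrier), `tsd` (per-carrier
#'   `tsd_call`s), `subfamily`, `divergence_pct` and
#'   `precise_parallel` (`TRUE`/`FALSE`/`NA`).
#' @export
classify_inspection <- function(alignment, pattern, consensus,
                                scheme = scoring_scheme(),
                                np_offset_threshold = 10,
                                n_fraction_threshold = 0.05,
                                library = NULL, presence = NULL,
                                flank = 600, nominal_insert = 300,
                                tsd_max_mismatch = 1,
                                fragment_share = 0.10) {
  stopifnot(inherits(alignment, "four_way_alignment"))
  if (is.null(names(pattern)) || !all(names(pattern) %in% names(GENOME_IDS)))
    stop("pattern must be named by ingroup genome ids")
  carriers <- names(pattern)[pattern]
  if (!length(carriers)) stop("pattern has no carriers")
  bad <- setdiff(carriers, c(names(alignment$rows), alignment$missing))
  if (length(bad))
    stop("pattern/alignment mismatch: no row for carrier ",
         paste(bad, collapse = ", "))

  out <- function(verdict, reason = "none", positions = NULL, tsd = NULL,
                  subfam = NULL, div = NULL, pp = NA) {
    structure(list(verdict = verdict, other_reason = reason,
                   positions = positions, tsd = tsd, subfamily = subfam,
                   divergence_pct = div, precise_parallel = pp),
              class = "inspection_outcome")
  }

  rows <- alignment$rows
  seqs <- vapply(rows, degap, character(1))

  ## 1. N content
  nfrac <- vapply(seqs, function(s) {
    if (!nzchar(s)) return(0)
    lengths(regmatches(s, gregexpr("N", s, fixed = TRUE))) / nchar(s)
  }, numeric(1))
  if (any(nfrac >= n_fraction_threshold))
    return(out("other", "has_N"))

  ## 2. missing or short rows
  expected <- names(pattern)
  if (length(intersect(expected, alignment$missing)))
    return(out("other", "truncated"))
  for (g in expected) {
    if (!g %in% names(rows)) return(out("other", "truncated"))
    need <- 0.8 * (2 * flank + if (pattern[[g]]) nominal_insert else 0)
    if (nchar(seqs[[g]]) < need) return(out("other", "truncated"))
  }

  ## presence alignments (reused from scoring when supplied)
  pres <- presence %||% setNames(lapply(names(rows), function(g) {
    score_alu_presence(rows[[g]], consensus, scheme)
  }), names(rows))

  ## 3. fragments of the element in nominally absent rows; checked against
  ## every library consensus (the retained fragments may be from any
  ## subfamily, and diagnostic sites break exact k-mers)
  probes <- unique(c(consensus, unname(library)))
  for (g in setdiff(names(pattern)[!pattern], alignment$missing)) {
    if (!g %in% names(rows)) next
    share <- max(vapply(probes, function(p)
      .kmer_fragment_share(seqs[[g]], p), numeric(1)))
    if (share >= fragment_share)
      return(out("other", "present_in_all"))
  }

  ## per-carrier insertion position (alignment column) and TSD
  positions <- setNames(rep(NA_integer_, length(carriers)), carriers)
  tsds <- setNames(vector("list", length(carriers)), carriers)
  for (g in carriers) {
    p <- pres[[g]]
    if (is.na(p$match_start)) next
    tail_end <- estimate_a_tail_end(seqs[[g]], p$match_end)
    positions[g] <- .row_pos_to_col(rows[[g]], p$match_start)
    tsds[[g]] <- detect_tsd(seqs[[g]], c(p$match_start, tail_end),
                            max_mismatch = tsd_max_mismatch)
  }

  ## subfamily per carrier
  subfam <- div <- NULL
  if (!is.null(library)) {
    subfam <- setNames(rep(NA_character_, length(carriers)), carriers)
    div <- setNames(rep(NA_real_, length(carriers)), carriers)
    for (g in carriers) {
      p <- pres[[g]]
      if (is.na(p$match_start)) next
      tail_end <- estimate_a_tail_end(seqs[[g]], p$match_end)
      aseq <- substr(seqs[[g]], p$match_start + 1, tail_end)
      sf <- assign_subfamily(aseq, library, scheme)
      subfam[g] <- sf$subfamily; div[g] <- sf$divergence_pct
    }
  }

  ## 4. near-parallel: position offsets or incompatible TSDs
  if (length(carriers) >= 2) {
    pos_ok <- positions[!is.na(positions)]
    if (length(pos_ok) >= 2 &&
        (max(pos_ok) - min(pos_ok)) > np_offset_threshold)
      return(out("near_parallel", positions = positions, tsd = tsds,
                 subfam = subfam, div = div))
    have_tsd <- carriers[!vapply(tsds[carriers], is.null, logical(1))]
    if (length(have_tsd) >= 2) {
      prs <- utils::combn(have_tsd, 2)
      for (k in seq_len(ncol(prs))) {
        if (!tsds_compatible(tsds[[prs[1, k]]], tsds[[prs[2, k]]],
                             tsd_max_mismatch))
          return(out("near_parallel", positions = positions, tsd = tsds,
                     subfam = subfam, div = div))
      }
    }
  }

  ## 5. shared validation: every carrier anchored by a TSD
  if (any(vapply(tsds[carriers], is.null, logical(1))) ||
      anyNA(positions))
    return(out("other", "truncated", positions = positions, tsd = tsds,
               subfam = subfam, div = div))
  pp <- NA
  if (!is.null(subfam) && length(carriers) >= 2)
    pp <- flag_precise_parallel(subfam)
  out("shared", positions = positions, tsd = tsds,
      subfam = subfam, div = div, pp = pp)
}
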