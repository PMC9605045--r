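## ---------------------------------------------------------------------------
## Consensus-based presence/absence scoring and category assignment.
## ---------------------------------------------------------------------------

#' Score one alignment row for Alu presence
#'
#' De-gaps the row and globally aligns the consensus against it under the
#' scoring scheme, with the consensus on the target side so that the
#' row's flanking overhang falls under the near-free target end-gap
#' scores while internal gaps (fragmented or deleted elements) stay
#' heavily penalized. The row is called present when the score reaches
#' `threshold_fraction` of the maximum attainable score
#' (`match * nchar(consensus)`).
#'
#' @param row Gapped or ungapped row sequence.
#' @param consensus Alu consensus sequence.
#' @param scheme A [scoring_scheme()].
#' @param threshold_fraction Fraction of the maximum score required for a
#'   presence call (default 0.5).
#' @return List with `score`, `present`, and `match_start`/`match_end`
#'   (0-based half-open interval on the de-gapped row spanned by the
#'   consensus alignment; `NA` for empty rows).
#' @export
score_alu_presence <- function(row, consensus, scheme = scoring_scheme(),
                               threshold_fraction = 0.5) {
  stopifnot(nchar(consensus) > 0)
  seq <- degap(row)
  if (!nzchar(seq))
    return(list(score = -Inf, present = FALSE,
                match_start = NA_integer_, match_end = NA_integer_))
  al <- align_pair(consensus, seq, scheme, traceback = TRUE)
  thr <- threshold_fraction * scheme$match * nchar(consensus)
  list(score = al$score, present = al$score >= thr,
       match_start = al$query_start, match_end = al$query_end)
}

#' Assign the presence/absence category label
#'
#' Concatenates the letters of the genomes carrying the insertion in fixed
#' (C, M, O, S) order. The all-absent pattern is invalid: a candidate
#' locus must show the element in at least one genome.
#'
#' @param pattern Logical vector of length 4 in (capuchin, marmoset,
#'   owl monkey, squirrel monkey) order.
#' @return One of the 15 category labels.
#' @examples
#' assign_category(c(TRUE, TRUE, TRUE, TRUE))    # "CMOS"
#' assign_category(c(TRUE, FALSE, FALSE, TRUE))  # "CS"
#' @export
assign_category <- function(pattern) {
  if (!is.logical(pattern) || length(pattern) != 4 || anyNA(pattern))
    stop("pattern must be a logical vector of length 4 without NAs")
  if (!any(pattern))
    stop("no insertion detected: the all-absent pattern is not a category")
  paste(unname(GENOME_IDS)[pattern], collapse = "")
}

## Table-2 style set numbering: (category, ascertainment genome) -> 1..24.
.SET_TABLE <- local({
  cats <- c("CM", "CO", "CS", "MO", "MS", "OS", "CMO", "CMS", "COS", "MOS")
  out <- list(); k <- 0L
  for (cat in cats) {
    for (letter in strsplit(cat, "", fixed = TRUE)[[1]]) {
      k <- k + 1L
      out[[paste(cat, letter, sep = ":")]] <- k
    }
  }
  out
})

#' Ascertainment set number for a (category, genome) pairing
#'
#' Numbers the 24 (shared category x ascertainment genome) pairings for the
#' ten multi-genome categories: CM ascertained from capuchin is set 1, CM
#' from marmoset set 2, and so on through MOS from squirrel monkey (set
#' 24). CMOS and single-genome categories have no set number (`NA`).
#'
#' @param category Category label.
#' @param genome Ingroup genome id (e.g. `"capuchin"`).
#' @return Integer set number or `NA`.
#' @export
set_number <- function(category, genome) {
  letter <- unname(GENOME_IDS[genome])
  .SET_TABLE[[paste(category, letter, sep = ":")]] %||% NA_integer_
}

#' Deduplicate candidate records ascertained from multiple genome sets
#'
#' The same insertion is typically ascertained from every carrier genome;
#' records whose projected insertion coordinates (on a shared reference)
#' fall within `overlap_tolerance` of each other on the same contig are
#' grouped, the record with the lowest set number is kept as the
#' representative, and the rest are counted as duplicates per (the
#' representative's) category. Grouping is performed on sorted
#' coordinates, so the result is independent of input order.
#'
#' @param records Data frame with at least `contig`, `ref_pos` (projected
#'   insertion coordinate), `set_number`, `category` columns; extra
#'   columns are carried through.
#' @param overlap_tolerance Maximum coordinate distance in bp for two
#'   records to count as the same insertion (default 50).
#' @return List with `unique` (representative rows, original columns plus
#'   `n_duplicates`), `duplicate_count` (named integer per category) and
#'   `total_duplicates`.
#' @export
dedupe_candidates <- function(records, overlap_tolerance = 50) {
  stopifnot(all(c("contig", "ref_pos", "set_number", "category") %in%
                  names(records)))
  if (!nrow(records))
    return(list(unique = records, duplicate_count = integer(0),
                total_duplicates = 0L))
  ## stable deterministic order, then chain-cluster by coordinate gaps
  ord <- order(records$contig, records$ref_pos,
               ifelse(is.na(records$set_number), 999L, records$set_number))
  r <- records[ord, , drop = FALSE]
  grp <- integer(nrow(r)); grp[1] <- 1L
  for (k in seq_len(nrow(r))[-1]) {
    same <- r$contig[k] == r$contig[k - 1] &&
      (r$ref_pos[k] - r$ref_pos[k - 1]) <= overlap_tolerance
    grp[k] <- if (same) grp[k - 1] else grp[k - 1] + 1L
  }
  reps <- integer(0); dup_cat <- character(0); ndup <- integer(0)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    sn <- ifelse(is.na(r$set_number[idx]), 999L, r$set_number[idx])
    rep_i <- idx[order(sn, r$ref_pos[idx])][1]
    reps <- c(reps, rep_i)
    dup_cat <- c(dup_cat, r$category[rep_i])
    ndup <- c(ndup, length(idx) - 1L)
  }
  uniq <- r[reps, , drop = FALSE]
  uniq$n_duplicates <- ndup
  dup_count <- tapply(ndup, dup_cat, sum)
  list(unique = uniq,
       duplicate_count = setNames(as.integer(dup_count), names(dup_count)),
       total_duplicates = sum(ndup))
}
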