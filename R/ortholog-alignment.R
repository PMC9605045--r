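## ---------------------------------------------------------------------------
## Ortholog anchoring and four-way alignment.
## ---------------------------------------------------------------------------

## summed aligned length of a PSL hit row
.hit_span <- function(hit) sum(hit$block_sizes[[1]])

## hits for one locus query, best first (max summed block length, ties by
## lexicographic target contig then lowest target start: deterministic)
.hits_for <- function(psl, locus_id) {
  h <- psl[psl$qName == locus_id, , drop = FALSE]
  if (!nrow(h)) return(h)
  spans <- vapply(seq_len(nrow(h)), function(k) sum(h$block_sizes[[k]]),
                  numeric(1))
  h[order(-spans, h$tName, h$tStart), , drop = FALSE]
}

#' Test lineage specificity of an Alu locus against the outgroup
#'
#' Given PSL hits of the extracted flank+element+flank query against the
#' outgroup genome, decides whether the element is absent from the
#' outgroup: both flanks must anchor colinearly to a single outgroup
#' location, and the unaligned query gap spanning the element position must
#' be an insertion-sized `[min_gap, max_gap]` bp with (near-)contiguous
#' target sequence behind it. A hit covering the whole query without such
#' a gap means the outgroup shares the element.
#'
#' @param locus An `alu_locus` from [extract_locus_with_flanks()].
#' @param outgroup_hits PSL data frame ([read_psl()]) of locus queries vs
#'   the outgroup genome.
#' @param min_gap,max_gap Accepted query-gap size in bp (defaults 250/500,
#'   roughly element + A-tail + TSD).
#' @param min_flank_cov Minimum fraction of each flank that must be
#'   covered by blocks of the anchoring hit (default 0.5).
#' @param max_target_gap Maximum target-side gap at the insertion point
#'   for it to count as a clean pre-integration site (default 20 bp).
#' @return List with `specific` (`TRUE`/`FALSE`/`NA`), `status`
#'   (`"lineage_specific"`, `"outgroup_present"`, `"gap_out_of_range"`,
#'   `"unmappable"`) and `gap` (observed query gap in bp or `NA`).
#' @export
check_lineage_specific <- function(locus, outgroup_hits,
                                   min_gap = 250, max_gap = 500,
                                   min_flank_cov = 0.5,
                                   max_target_gap = 20) {
  stopifnot(inherits(locus, "alu_locus"))
  h <- .hits_for(outgroup_hits, locus$locus_id)
  if (!nrow(h))
    return(list(specific = NA, status = "unmappable", gap = NA_integer_))
  flank <- locus$flank_length
  qsize <- h$qSize[1]
  for (k in seq_len(nrow(h))) {
    bs <- h$block_sizes[[k]]; qs <- h$q_starts[[k]]; ts <- h$t_starts[[k]]
    cov <- function(lo, hi) {
      sum(pmax(0, pmin(qs + bs, hi) - pmax(qs, lo))) / (hi - lo)
    }
    if (cov(0, flank) < min_flank_cov ||
        cov(qsize - flank, qsize) < min_flank_cov) next
    ## co-anchoring hit found: inspect the gap structure over the element
    if (length(bs) > 1) {
      qgaps <- qs[-1] - (qs[-length(qs)] + bs[-length(bs)])
      tgaps <- ts[-1] - (ts[-length(ts)] + bs[-length(bs)])
      gap_end <- qs[-1]; gap_start <- qs[-length(qs)] + bs[-length(bs)]
      spans_alu <- gap_start <= (qsize - flank) & gap_end >= flank
      cand <- which(spans_alu & tgaps <= max_target_gap & qgaps > 0)
      if (length(cand)) {
        g <- max(qgaps[cand])
        if (g >= min_gap && g <= max_gap)
          return(list(specific = TRUE, status = "lineage_specific", gap = g))
        if (g > max_gap)
          return(list(specific = FALSE, status = "gap_out_of_range", gap = g))
        return(list(specific = FALSE, status = "outgroup_present", gap = g))
      }
    }
    return(list(specific = FALSE, status = "outgroup_present", gap = 0L))
  }
  list(specific = NA, status = "unmappable", gap = NA_integer_)
}

#' Fetch orthologous regions from the other genomes
#'
#' For each genome, selects the best colinear PSL hit of the locus query
#' (maximal summed block length; ties broken by lexicographic target
#' contig then lowest target coordinate) and extracts the target region
#' spanning the projected query, including any intervening
#' insertion-sized target sequence. Genomes without a qualifying hit are
#' marked missing and flow on to inspection as truncated.
#'
#' @param locus An `alu_locus`.
#' @param genomes Named list of genomes (each a named character vector of
#'   contigs).
#' @param hits_by_genome Named list of PSL data frames, one per target
#'   genome.
#' @return Named list with one element per target genome: either a list
#'   `(sequence, contig, start, end)` or `NULL` when missing.
#' @export
fetch_orthologs <- function(locus, genomes, hits_by_genome) {
  out <- setNames(vector("list", length(hits_by_genome)),
                  names(hits_by_genome))
  for (g in names(hits_by_genome)) {
    h <- .hits_for(hits_by_genome[[g]], locus$locus_id)
    if (!nrow(h)) next
    bs <- h$block_sizes[[1]]; qs <- h$q_starts[[1]]; ts <- h$t_starts[[1]]
    nb <- length(bs)
    proj0 <- ts[1] - qs[1]
    proj1 <- (ts[nb] + bs[nb]) + (h$qSize[1] - (qs[nb] + bs[nb]))
    contig <- h$tName[1]
    seq <- genomes[[g]][[contig]]
    lo <- max(0L, proj0); hi <- min(nchar(seq), proj1)
    if (hi <= lo) next
    out[[g]] <- list(sequence = substr(seq, lo + 1, hi),
                     contig = contig, start = lo, end = hi)
  }
  out
}

#' Build the four-way orthologous alignment
#'
#' Multiple alignment of 2-4 orthologous sequences by star-progressive
#' merging: the ascertainment genome's sequence is the center, each other
#' sequence is aligned to it pairwise under the scoring scheme, and the
#' pairwise gap structures are merged by the usual "once a gap, always a
#' gap" rule. The ungapped content of every row is identical to its input
#' sequence.
#'
#' @param sequences Named list/vector of 2-4 nucleotide strings.
#' @param scheme A [scoring_scheme()].
#' @param center Name of the center (ascertainment) sequence; defaults to
#'   the first.
#' @return Object of class `four_way_alignment`: list with `rows` (named
#'   character vector of gapped sequences), `column_count`,
#'   `source_genome`, `aligner` (`"internal"`) and `missing` (ingroup
#'   genomes absent from the alignment).
#' @export
align_four_way <- function(sequences, scheme = scoring_scheme(),
                           center = NULL) {
  sequences <- as.list(sequences)
  if (length(sequences) < 2)
    stop("align_four_way needs at least 2 sequences")
  if (is.null(center)) center <- names(sequences)[1]
  stopifnot(center %in% names(sequences))
  cseq <- sequences[[center]]
  others <- setdiff(names(sequences), center)
  L <- nchar(cseq)

  pws <- lapply(others, function(g) {
    ## near-colinear orthologs: band the search around the diagonal,
    ## leaving room for one insertion-sized indel beyond the length
    ## difference; align_pair falls back to the full matrix if needed
    bw <- abs(L - nchar(sequences[[g]])) + 200L
    align_pair(cseq, sequences[[g]], scheme, traceback = TRUE, band = bw)
  })
  names(pws) <- others

  ## per-pairwise gap counts around each center residue (index 0..L)
  gapcounts <- lapply(pws, function(al) {
    cg <- strsplit(al$target_gapped, "", fixed = TRUE)[[1]]
    npos <- which(cg != "-")
    c(npos[1] - 1L, diff(npos) - 1L, length(cg) - npos[length(npos)])
  })
  G <- Reduce(pmax, gapcounts)

  cchars <- strsplit(cseq, "", fixed = TRUE)[[1]]
  center_row <- paste0(
    strrep("-", G[1]),
    paste0(vapply(seq_len(L), function(p) {
      paste0(cchars[p], strrep("-", G[p + 1L]))
    }, character(1)), collapse = ""))

  rows <- setNames(character(length(sequences)), names(sequences))
  rows[center] <- center_row
  for (g in others) {
    al <- pws[[g]]
    cg <- strsplit(al$target_gapped, "", fixed = TRUE)[[1]]
    og <- strsplit(al$query_gapped, "", fixed = TRUE)[[1]]
    npos <- which(cg != "-")
    bounds <- c(0L, npos, length(cg) + 1L)
    chunks <- character(L + 1L)
    for (p in 0:L) {
      lo <- bounds[p + 1L] + 1L; hi <- bounds[p + 2L] - 1L
      chunk <- if (hi >= lo) paste(og[lo:hi], collapse = "") else ""
      chunks[p + 1L] <- paste0(chunk, strrep("-", G[p + 1L] - (hi - lo + 1L)))
    }
    res_chars <- og[npos]
    body <- paste0(vapply(seq_len(L), function(p) {
      paste0(res_chars[p], chunks[p + 1L])
    }, character(1)), collapse = "")
    rows[g] <- paste0(chunks[1L], body)
  }

  cc <- unique(nchar(rows))
  stopifnot(length(cc) == 1L)
  structure(list(rows = rows, column_count = cc, source_genome = center,
                 aligner = "internal",
                 missing = setdiff(names(GENOME_IDS), names(rows))),
            class = "four_way_alignment")
}

#' Alignment length filter
#'
#' Keeps only alignments whose column count lies in the inclusive
#' `[min, max]` window: the ideal flank+element+flank span is ~1500 bp and
#' longer alignments indicate extra intervening sequence.
#'
#' @param alignment A `four_way_alignment`.
#' @param min,max Inclusive column-count bounds (defaults 1500/1600).
#' @return `TRUE` if the alignment passes.
#' @export
filter_alignment_length <- function(alignment, min = 1500, max = 1600) {
  stopifnot(inherits(alignment, "four_way_alignment"))
  alignment$column_count >= min && alignment$column_count <= max
}
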