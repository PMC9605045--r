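#' Parse RepeatMasker .out annotations
#'
#' Reads the standard RepeatMasker `.out` layout (three header lines, then
#' one whitespace-delimited record per line). Genomic coordinates are
#' normalized to 0-based half-open intervals. Consensus coordinates, which
#' the format reports 1-based and, for minus-strand hits, in the
#' `(left) end begin` convention, are normalized to a single
#' `consensus_offset`: the number of consensus bases missing 5' of the
#' match (i.e. `begin - 1`).
#'
#' @param path Path to a `.out` file (or a character vector of its lines).
#' @param genome_id Genome identifier stored with each record.
#' @return Data frame with one row per annotation: `genome_id`, `contig`,
#'   `start`, `end` (0-based half-open), `strand` (`"+"`/`"-"`),
#'   `repeat_name`, `repeat_class`, `consensus_offset`, `divergence_pct`.
#' @export
parse_repeat_annotations <- function(path, genome_id = NA_character_) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path) else path
  if (length(lines) <= 3L)
    return(data.frame(genome_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), repeat_name = character(0),
                      repeat_class = character(0),
                      consensus_offset = integer(0),
                      divergence_pct = numeric(0),
                      stringsAsFactors = FALSE))
  body <- lines[-(1:3)]
  body_no <- which(nzchar(trimws(body))) + 3L
  body <- body[nzchar(trimws(body))]
  recs <- vector("list", length(body))
  for (k in seq_along(body)) {
    f <- strsplit(trimws(body[k]), "\\s+")[[1]]
    if (length(f) < 14L)
      stop("malformed RepeatMasker .out record at line ", body_no[k],
           ": expected >= 14 fields, got ", length(f))
    qbegin <- suppressWarnings(as.integer(f[6]))
    qend <- suppressWarnings(as.integer(f[7]))
    strand <- f[9]
    if (is.na(qbegin) || is.na(qend) || !strand %in% c("+", "C"))
      stop("malformed RepeatMasker .out record at line ", body_no[k])
    if (strand == "+") {
      begin <- suppressWarnings(as.integer(f[12]))
    } else {
      ## minus strand: fields are (left) end begin
      begin <- suppressWarnings(as.integer(f[14]))
    }
    if (is.na(begin) || begin < 1)
      stop("malformed consensus coordinates at line ", body_no[k])
    recs[[k]] <- data.frame(
      genome_id = genome_id, contig = f[5],
      start = qbegin - 1L, end = qend,
      strand = if (strand == "C") "-" else "+",
      repeat_name = f[10], repeat_class = f[11],
      consensus_offset = begin - 1L,
      divergence_pct = suppressWarnings(as.numeric(f[2])),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  if (any(out$start >= out$end))
    stop("invalid interval (start >= end) in RepeatMasker .out input")
  out
}

#' Write annotations in RepeatMasker .out layout
#'
#' Inverse of [parse_repeat_annotations()] for simulator output: emits the
#' three standard header lines followed by whitespace-delimited records
#' with 1-based inclusive genomic coordinates and the native consensus
#' column conventions.
#'
#' @param ann Data frame with columns `contig`, `qbegin`, `qend`, `strand`,
#'   `repeat_name`, `repeat_class`, `rbegin`, `rend`, `rleft` (1-based
#'   inclusive, as written by the simulator).
#' @param path Output file.
#' @param divergence_pct Divergence percentage written in column 2.
#' @return `path`, invisibly.
#' @export
write_repeat_annotations <- function(ann, path, divergence_pct = 0) {
  hdr <- c(
    paste("  SW   perc perc perc  query    position in query     matching",
          "      repeat         position in repeat"),
    paste("score   div. del. ins.  sequence   begin    end   (left)  ",
          "repeat         class/family    begin   end  (left)   ID"),
    "")
  lines <- hdr
  if (!is.null(ann) && nrow(ann)) {
    for (k in seq_len(nrow(ann))) {
      r <- ann[k, ]
      qleft <- ""  # (left in query) unused downstream; keep placeholder
      if (r$strand %in% c("+")) {
        cons <- sprintf("%d %d (%d)", r$rbegin, r$rend, r$rleft)
      } else {
        cons <- sprintf("(%d) %d %d", r$rleft, r$rend, r$rbegin)
      }
      lines <- c(lines, sprintf(
        "%5d %6.1f  0.0  0.0  %s %8d %8d (0) %s  %-10s %-14s %s %d",
        2000L, divergence_pct, r$contig, r$qbegin, r$qend,
        if (r$strand == "+") "+" else "C",
        r$repeat_name, r$repeat_class, cons, k))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Select full-length Alu annotations
#'
#' Keeps Alu-class records whose genomic span is at least `min_length` and
#' whose match begins no more than `max_consensus_offset` bases from the
#' 5' start of the consensus. Both bounds are inclusive; input order is
#' preserved and the filter is idempotent.
#'
#' @param annotations Data frame from [parse_repeat_annotations()].
#' @param min_length Minimum genomic span in bp (default 267).
#' @param max_consensus_offset Maximum missing 5' consensus bases
#'   (default 4).
#' @return The filtered data frame.
#' @export
select_full_length <- function(annotations, min_length = 267,
                               max_consensus_offset = 4) {
  sel <- startsWith(annotations$repeat_class, "SINE/Alu") &
    (annotations$end - annotations$start) >= min_length &
    annotations$consensus_offset <= max_consensus_offset
  annotations[sel, , drop = FALSE]
}

#' Extract an Alu locus with fixed-length flanks
#'
#' Cuts the element plus `flank` bp of 5' and 3' flanking sequence out of
#' the genome. A locus whose contig cannot supply a full flank on either
#' side is rejected with status `"edge_locus"` rather than silently
#' shortened. Minus-strand elements are reverse-complemented (and their
#' flanks swapped) so that `sequence_alu` is always in consensus
#' orientation.
#'
#' @param genome Named character vector (or `DNAStringSet`) of contigs.
#' @param annotation Single-row data frame from
#'   [parse_repeat_annotations()].
#' @param flank Flank length in bp (default 600).
#' @return An object of class `alu_locus` with fields `status`
#'   (`"ok"`/`"edge_locus"`), `locus_id`, `genome_id`, `contig`,
#'   `alu_start`, `alu_end`, `strand`, `subfamily_call`,
#'   `sequence_5flank`, `sequence_alu`, `sequence_3flank`,
#'   `flank_length`, `window_start`, `window_end` and `query` (the
#'   concatenated flank+element+flank string).
#' @export
extract_locus_with_flanks <- function(genome, annotation, flank = 600) {
  if (inherits(genome, "DNAStringSet"))
    genome <- setNames(as.character(genome), names(genome))
  contig <- annotation$contig
  if (!contig %in% names(genome))
    stop("contig not found in genome: ", contig)
  seq <- genome[[contig]]
  s <- annotation$start; e <- annotation$end
  w0 <- s - flank; w1 <- e + flank
  mk <- function(status, f5 = NA, alu = NA, f3 = NA) {
    q <- if (status == "ok") paste0(f5, alu, f3) else NA_character_
    structure(list(
      status = status,
      locus_id = sprintf("%s:%s:%d-%d", annotation$genome_id, contig, w0, w1),
      genome_id = annotation$genome_id, contig = contig,
      alu_start = s, alu_end = e, strand = annotation$strand,
      subfamily_call = annotation$repeat_name,
      sequence_5flank = f5, sequence_alu = alu, sequence_3flank = f3,
      flank_length = flank, window_start = w0, window_end = w1,
      query = q), class = "alu_locus")
  }
  if (w0 < 0 || w1 > nchar(seq)) return(mk("edge_locus"))
  f5 <- substr(seq, w0 + 1, s)
  alu <- substr(seq, s + 1, e)
  f3 <- substr(seq, e + 1, w1)
  if (annotation$strand == "-") {
    tmp <- revcomp_chr(f5)
    f5 <- revcomp_chr(f3); f3 <- tmp; alu <- revcomp_chr(alu)
  }
  mk("ok", f5, alu, f3)
}
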