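#' Pairwise alignment scoring scheme
#'
#' The asymmetric affine gap scheme used throughout the pipeline, both for
#' building orthologous alignments and for scoring Alu presence against a
#' consensus. Gaps are scored by the sequence they fall in (a dash in the
#' target row is a "target gap"; a dash in the query row is a "query gap")
#' and by position class (left overhang, internal, right overhang). A gap
#' of length L costs `open + (L - 1) * extend`.
#'
#' The defaults are deliberately lopsided: end overhangs in the target are
#' nearly free (so a short consensus can be dropped onto a long genomic
#' region and only its own span is judged), while internal gaps on either
#' side cost -5 to open and -3 to extend (so fragmented or deleted elements
#' score far below an intact copy).
#'
#' @param match Match score (default 1.3).
#' @param mismatch Mismatch score (default 0).
#' @param ... Named overrides for any of the twelve gap scores:
#'   `target_left_open`, `target_left_extend`, `target_internal_open`,
#'   `target_internal_extend`, `target_right_open`, `target_right_extend`,
#'   and the six `query_*` counterparts.
#' @return An object of class `alu_scoring_scheme` (a named list).
#' @examples
#' sch <- scoring_scheme()
#' align_pair("ACGT", "ACGT", sch)$score  # 4 * 1.3
#' @export
scoring_scheme <- function(match = 1.3, mismatch = 0, ...) {
  scheme <- list(
    match = match,
    mismatch = mismatch,
    target_left_open = -2, target_left_extend = 0,
    target_right_open = -1, target_right_extend = 0,
    target_internal_open = -5, target_internal_extend = -3,
    query_left_open = -1, query_left_extend = -1,
    query_right_open = -2, query_right_extend = 0,
    query_internal_open = -5, query_internal_extend = -3
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(scheme))
  if (length(bad))
    stop("unknown scoring parameter(s): ", paste(bad, collapse = ", "))
  scheme[names(dots)] <- dots
  stopifnot(all(vapply(scheme, is.numeric, logical(1))))
  structure(scheme, class = "alu_scoring_scheme")
}

#' Global pairwise alignment under the pipeline scoring scheme
#'
#' @param target,query Nucleotide strings (target is the first/reference
#'   sequence; consensus sequences are conventionally placed on the target
#'   side so that the genomic region's overhang falls under the cheap
#'   target end-gap scores).
#' @param scheme A [scoring_scheme()].
#' @param traceback If `FALSE`, only the score is computed (faster).
#' @param band Optional diagonal band half-width in columns restricting
#'   the search to near-colinear alignments (0 = full matrix). If the
#'   band proves too narrow for the optimal path it is dropped and the
#'   full matrix is used.
#' @return A list with `score`, and when `traceback = TRUE` also
#'   `target_gapped`, `query_gapped`, `query_start`/`query_end` (0-based
#'   half-open query interval spanned by the target's residues),
#'   `matches`, `mismatches` and `aligned_cols`.
#' @export
align_pair <- function(target, query, scheme = scoring_scheme(),
                       traceback = TRUE, band = 0) {
  stopifnot(inherits(scheme, "alu_scoring_scheme"),
            is.character(target), is.character(query),
            length(target) == 1L, length(query) == 1L)
  if (!nzchar(target) || !nzchar(query))
    stop("align_pair: both sequences must be non-empty")
  if (band > 0) {
    res <- tryCatch(
      align_pair_cpp(target, query, unclass(scheme), traceback,
                     as.integer(band)),
      error = function(e) NULL)
    if (!is.null(res)) return(res)
  }
  align_pair_cpp(target, query, unclass(scheme), traceback, 0L)
}
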