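## ---------------------------------------------------------------------------
## Summary tables: per-category candidate / duplicate / unique / inspection
## counts with rendered percentages, and pooled PCR confirmation rates.
## ---------------------------------------------------------------------------

.fmt_pct <- function(num, den, digits = 0) {
  if (is.na(den) || den == 0) return("—")
  v <- round_half_up(100 * num / den, digits)
  if (digits == 0) sprintf("%d%%", as.integer(v))
  else sprintf(paste0("%.", digits, "f%%"), v)
}

#' Summarize categorized, inspected candidate loci
#'
#' Builds the per-category summary table: total candidates, duplicates
#' across ascertainment sets, unique calls, post-inspection shared /
#' near-parallel / other counts, the percent of unique calls retained as
#' shared per category (integer percent), and grand totals with the
#' shared/NP/other fractions of all unique calls (one decimal).
#' Percentages are rounded half-up at display precision.
#'
#' Accepts either per-record input (one row per unique candidate, columns
#' `category`, `verdict`, optionally `n_duplicates`) or a pre-aggregated
#' count table (columns `category`, `total_candidates`, `duplicates`,
#' `post_shared`, `post_np`, `post_other`). Per-record input with a
#' missing/NA verdict is an error: every unique call must be inspected.
#'
#' @param x Data frame in one of the two layouts above.
#' @param categories Category column order (default the ten multi-genome
#'   categories; other labels present in the data are appended).
#' @return Object of class `category_summary`: list with `table` (one row
#'   per category), `totals` (grand totals incl. `shared_pct`, `np_pct`,
#'   `other_pct` numeric and rendered) .
#' @export
summarize <- function(x, categories = REPORT_CATEGORIES) {
  stopifnot(is.data.frame(x), "category" %in% names(x))
  counts_layout <- all(c("total_candidates", "duplicates", "post_shared",
                         "post_np", "post_other") %in% names(x))
  if (!counts_layout) {
    if (!"verdict" %in% names(x))
      stop("per-record input needs a 'verdict' column")
    if (anyNA(x$verdict))
      stop("record without inspection outcome")
    if (!"n_duplicates" %in% names(x)) x$n_duplicates <- rep(0L, nrow(x))
    cats <- unique(c(categories, x$category))
    agg <- lapply(cats, function(cat) {
      r <- x[x$category == cat, , drop = FALSE]
      data.frame(category = cat,
                 total_candidates = nrow(r) + sum(r$n_duplicates),
                 duplicates = sum(r$n_duplicates),
                 post_shared = sum(r$verdict == "shared"),
                 post_np = sum(r$verdict == "near_parallel"),
                 post_other = sum(r$verdict == "other"),
                 stringsAsFactors = FALSE)
    })
    x <- do.call(rbind, agg)
  } else {
    cats <- unique(c(intersect(categories, x$category),
                     setdiff(x$category, categories)))
    x <- x[match(cats, x$category), , drop = FALSE]
  }
  x$unique_calls <- x$total_candidates - x$duplicates
  bad <- which(x$post_shared + x$post_np + x$post_other != x$unique_calls)
  if (length(bad))
    stop("inspection counts do not sum to unique calls for category ",
         paste(x$category[bad], collapse = ", "))
  x$pct_retained <- vapply(seq_len(nrow(x)), function(k) {
    .fmt_pct(x$post_shared[k], x$unique_calls[k], 0)
  }, character(1))
  tot <- list(
    total_candidates = sum(x$total_candidates),
    duplicates = sum(x$duplicates),
    unique_calls = sum(x$unique_calls),
    post_shared = sum(x$post_shared),
    post_np = sum(x$post_np),
    post_other = sum(x$post_other))
  u <- tot$unique_calls
  tot$shared_pct <- if (u) round_half_up(100 * tot$post_shared / u, 1) else NA
  tot$np_pct <- if (u) round_half_up(100 * tot$post_np / u, 1) else NA
  tot$other_pct <- if (u) round_half_up(100 * tot$post_other / u, 1) else NA
  tot$shared_pct_str <- .fmt_pct(tot$post_shared, u, 1)
  tot$np_pct_str <- .fmt_pct(tot$post_np, u, 1)
  tot$other_pct_str <- .fmt_pct(tot$post_other, u, 1)
  structure(list(table = x, totals = tot), class = "category_summary")
}

#' @export
print.category_summary <- function(x, ...) {
  cat("Per-category candidate summary\n")
  print(x$table, row.names = FALSE)
  with(x$totals, cat(sprintf(
    "Totals: %d unique calls; shared %d (%s), NP %d (%s), other %d (%s)\n",
    unique_calls, post_shared, shared_pct_str, post_np, np_pct_str,
    post_other, other_pct_str)))
  invisible(x)
}

#' Write a category summary as TSV (and optionally JSON)
#'
#' @param x A `category_summary`.
#' @param path_tsv TSV output path.
#' @param path_json Optional JSON output path.
#' @return `path_tsv`, invisibly.
#' @export
write_category_summary <- function(x, path_tsv, path_json = NULL) {
  stopifnot(inherits(x, "category_summary"))
  write.table(x$table, path_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(list(table = x$table, totals = x$totals),
                         path_json, auto_unbox = TRUE, digits = NA)
  invisible(path_tsv)
}

#' Pool PCR confirmation results across categories
#'
#' @param analyzed Named integer vector: loci analyzed by PCR per
#'   category.
#' @param confirmed Named integer vector: loci confirmed per category
#'   (same names).
#' @param post_shared Optional named integer vector of post-inspection
#'   shared counts; when given, `analyzed <= post_shared` is enforced.
#' @return Object of class `pcr_summary`: list with `table` (per-category
#'   counts and rendered `x/y (z%)` strings), `pooled_confirmed`,
#'   `pooled_analyzed`, `pooled_pct` (integer percent, half-up) and
#'   `pooled_str`.
#' @export
pool_pcr <- function(analyzed, confirmed, post_shared = NULL) {
  stopifnot(length(analyzed) == length(confirmed),
            identical(names(analyzed), names(confirmed)))
  if (any(analyzed < 0) || any(confirmed < 0))
    stop("counts must be non-negative")
  if (any(confirmed > analyzed))
    stop("confirmed cannot exceed analyzed",
         if (any(analyzed == 0 & confirmed > 0))
           " (confirmed > 0 with analyzed = 0)" else "")
  if (!is.null(post_shared) && any(analyzed > post_shared[names(analyzed)]))
    stop("analyzed cannot exceed post-inspection shared counts")
  per <- vapply(seq_along(analyzed), function(k) {
    if (analyzed[k] == 0) return("—")
    sprintf("%d/%d (%s)", confirmed[k], analyzed[k],
            .fmt_pct(confirmed[k], analyzed[k], 0))
  }, character(1))
  tab <- data.frame(category = names(analyzed),
                    analyzed = as.integer(analyzed),
                    confirmed = as.integer(confirmed),
                    confirmed_str = per, stringsAsFactors = FALSE)
  if (!is.null(post_shared))
    tab$post_shared <- as.integer(post_shared[names(analyzed)])
  ca <- sum(confirmed); aa <- sum(analyzed)
  pooled_pct <- if (aa) round_half_up(100 * ca / aa, 0) else NA_real_
  structure(list(
    table = tab, pooled_confirmed = ca, pooled_analyzed = aa,
    pooled_pct = pooled_pct,
    pooled_str = if (aa) sprintf("%d/%d (%d%%)", ca, aa,
                                 as.integer(pooled_pct)) else "—"),
    class = "pcr_summary")
}

#' @export
print.pcr_summary <- function(x, ...) {
  cat("PCR confirmation summary\n")
  print(x$table, row.names = FALSE)
  cat("Pooled:", x$pooled_str, "\n")
  invisible(x)
}
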