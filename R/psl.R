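#' Read PSL (BLAT) alignment hits
#'
#' Parses the 21-column tab/whitespace-delimited PSL format (0-based
#' half-open coordinates). A `psLayout` header, if present, is skipped.
#' The three comma-separated block columns are parsed into integer list
#' columns `block_sizes`, `q_starts`, `t_starts`; blocks are checked to be
#' non-overlapping and ascending in both coordinate systems.
#'
#' @param path Path to a `.psl` file (or a character vector of its lines).
#' @return Data frame with the standard scalar columns plus the three
#'   list columns.
#' @export
read_psl <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  ## drop header lines (psLayout variant): keep lines whose first field is
  ## an integer
  keep <- grepl("^\\s*\\d", lines)
  lines <- lines[keep]
  empty <- data.frame(matches = integer(0), strand = character(0),
                      qName = character(0), qSize = integer(0),
                      qStart = integer(0), qEnd = integer(0),
                      tName = character(0), tSize = integer(0),
                      tStart = integer(0), tEnd = integer(0),
                      blockCount = integer(0), stringsAsFactors = FALSE)
  if (!length(lines)) {
    empty$block_sizes <- list(); empty$q_starts <- list()
    empty$t_starts <- list()
    return(empty)
  }
  parse_ints <- function(x) as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
  rows <- lapply(seq_along(lines), function(k) {
    f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(f) < 21L)
      stop("malformed PSL record (", length(f), " fields) at data line ", k)
    bs <- parse_ints(f[19]); qs <- parse_ints(f[20]); ts <- parse_ints(f[21])
    if (length(bs) != length(qs) || length(bs) != length(ts))
      stop("inconsistent block lists in PSL record at data line ", k)
    if (length(bs) > 1) {
      if (any(diff(qs) < head(bs, -1)) || any(diff(ts) < head(bs, -1)))
        stop("PSL blocks overlap or are not ascending at data line ", k)
    }
    list(matches = as.integer(f[1]), strand = f[9], qName = f[10],
         qSize = as.integer(f[11]), qStart = as.integer(f[12]),
         qEnd = as.integer(f[13]), tName = f[14], tSize = as.integer(f[15]),
         tStart = as.integer(f[16]), tEnd = as.integer(f[17]),
         blockCount = as.integer(f[18]),
         block_sizes = bs, q_starts = qs, t_starts = ts)
  })
  df <- data.frame(
    matches = vapply(rows, `[[`, integer(1), "matches"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    qName = vapply(rows, `[[`, character(1), "qName"),
    qSize = vapply(rows, `[[`, integer(1), "qSize"),
    qStart = vapply(rows, `[[`, integer(1), "qStart"),
    qEnd = vapply(rows, `[[`, integer(1), "qEnd"),
    tName = vapply(rows, `[[`, character(1), "tName"),
    tSize = vapply(rows, `[[`, integer(1), "tSize"),
    tStart = vapply(rows, `[[`, integer(1), "tStart"),
    tEnd = vapply(rows, `[[`, integer(1), "tEnd"),
    blockCount = vapply(rows, `[[`, integer(1), "blockCount"),
    stringsAsFactors = FALSE)
  df$block_sizes <- lapply(rows, `[[`, "block_sizes")
  df$q_starts <- lapply(rows, `[[`, "q_starts")
  df$t_starts <- lapply(rows, `[[`, "t_starts")
  df
}

#' Write PSL alignment hits
#'
#' @param psl Data frame in the column layout produced by the simulator
#'   (scalar 21-column form with comma-joined block columns).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_psl <- function(psl, path) {
  cols <- c("matches", "misMatches", "repMatches", "nCount", "qNumInsert",
            "qBaseInsert", "tNumInsert", "tBaseInsert", "strand", "qName",
            "qSize", "qStart", "qEnd", "tName", "tSize", "tStart", "tEnd",
            "blockCount", "blockSizes", "qStarts", "tStarts")
  stopifnot(all(cols %in% names(psl)))
  write.table(psl[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
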