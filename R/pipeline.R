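## ---------------------------------------------------------------------------
## End-to-end pipeline driver over a simulated (or equivalently structured
## real-mode) input directory, plus truth-recovery evaluation helpers.
## ---------------------------------------------------------------------------

#' Load a pipeline input directory
#'
#' Reads `genomes/*.fa`, `annotations/*.out` and `anchors/*_vs_*.psl`
#' (the layout written by [simulate_cohort()] / [write_cohort()]), plus
#' `truth.tsv` when present.
#'
#' @param dir Input directory.
#' @return List with `genomes`, `annotations` (per-genome list),
#'   `psl` (per `src|tgt` pair) and `truth` (or `NULL`).
#' @export
load_cohort_dir <- function(dir) {
  fa <- list.files(file.path(dir, "genomes"), pattern = "\\.fa$",
                   full.names = TRUE)
  if (!length(fa)) stop("no genomes/*.fa found under ", dir)
  genomes <- setNames(lapply(fa, function(f) {
    xs <- Biostrings::readDNAStringSet(f)
    setNames(as.character(xs), sub("\\s.*", "", names(xs)))
  }), sub("\\.fa$", "", basename(fa)))
  anns <- setNames(lapply(names(genomes), function(g) {
    f <- file.path(dir, "annotations", paste0(g, ".out"))
    if (file.exists(f)) parse_repeat_annotations(f, g) else NULL
  }), names(genomes))
  psl_files <- list.files(file.path(dir, "anchors"), pattern = "\\.psl$",
                          full.names = TRUE)
  psl <- setNames(lapply(psl_files, read_psl),
                  sub("_vs_", "|", sub("\\.psl$", "", basename(psl_files))))
  truth_f <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_f))
    read.table(truth_f, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE) else NULL
  list(genomes = genomes, annotations = anns, psl = psl, truth = truth)
}

#' Run the full presence/absence categorization pipeline
#'
#' For every genome: parse repeat annotations, keep full-length Alu
#' elements, extract each with 600 bp flanks, test lineage specificity
#' against the outgroup, fetch orthologs from the other three ingroup
#' genomes, build the four-way alignment, apply the 1500-1600 column
#' filter, score presence per genome against the consensus and assign the
#' category. Candidates are then deduplicated across ascertainment sets
#' and every unique call is run through automated inspection.
#'
#' Deduplication uses each candidate's element start coordinate on its
#' own genome; simulated locus regions are colinear across genomes, and
#' real-mode callers should project coordinates onto a common reference
#' before this step.
#'
#' @param input A directory path (layout of [write_cohort()]) or the list
#'   from [load_cohort_dir()].
#' @param consensus Consensus used for presence scoring (default: the
#'   bundled mock AluSc).
#' @param scheme A [scoring_scheme()].
#' @param library Subfamily library for inspection (default bundled mock
#'   library).
#' @param flank Flank length in bp (default 600).
#' @param min_len,max_len Alignment column-count window (1500/1600).
#' @param overlap_tolerance Dedup coordinate tolerance in bp (default 50).
#' @param threshold_fraction Presence threshold (default 0.5).
#' @param verbose Print progress.
#' @return Object of class `alu_pipeline_result`: list with `records`
#'   (per-candidate data frame), `unique` (post-dedup records with
#'   inspection columns), `dedup`, `summary` (a `category_summary` over
#'   the ten reporting categories), `n_candidates`, and `truth` when the
#'   input carried one.
#' @export
run_pipeline <- function(input, consensus = default_subfamily_library()[[1]],
                         scheme = scoring_scheme(),
                         library = default_subfamily_library(),
                         flank = 600, min_len = 1500, max_len = 1600,
                         overlap_tolerance = 50, threshold_fraction = 0.5,
                         verbose = FALSE) {
  dat <- if (is.character(input)) load_cohort_dir(input) else input
  ingroup <- intersect(names(GENOME_IDS), names(dat$genomes))
  rec_rows <- list(); details <- list()

  for (g in ingroup) {
    ann <- dat$annotations[[g]]
    if (is.null(ann) || !nrow(ann)) next
    full <- select_full_length(ann)
    if (!nrow(full)) next
    out_psl <- dat$psl[[paste(g, OUTGROUP_ID, sep = "|")]]
    for (k in seq_len(nrow(full))) {
      locus <- extract_locus_with_flanks(dat$genomes[[g]], full[k, ], flank)
      rec <- list(locus_id = locus$locus_id, genome = g,
                  contig = locus$contig, ref_pos = locus$alu_start,
                  status = locus$status, category = NA_character_,
                  set_number = NA_integer_, pattern = NA_character_,
                  column_count = NA_integer_, passed_filter = NA,
                  verdict = NA_character_, other_reason = NA_character_)
      if (locus$status != "ok") {
        rec$status <- "edge_locus"
        rec_rows[[length(rec_rows) + 1L]] <- rec
        next
      }
      ls <- check_lineage_specific(locus, out_psl %||% read_psl(character(0)))
      if (!isTRUE(ls$specific)) {
        rec$status <- paste0("not_specific:", ls$status)
        rec_rows[[length(rec_rows) + 1L]] <- rec
        next
      }
      hits_by_genome <- setNames(lapply(setdiff(ingroup, g), function(o) {
        dat$psl[[paste(g, o, sep = "|")]] %||% read_psl(character(0))
      }), setdiff(ingroup, g))
      orth <- fetch_orthologs(locus, dat$genomes, hits_by_genome)
      seqs <- c(setNames(list(locus$query), g),
                lapply(orth[!vapply(orth, is.null, logical(1))],
                       `[[`, "sequence"))
      aln <- align_four_way(seqs, scheme, center = g)
      rec$column_count <- aln$column_count
      rec$passed_filter <- filter_alignment_length(aln, min_len, max_len)
      if (!rec$passed_filter) {
        rec$status <- "length_filtered"
        rec_rows[[length(rec_rows) + 1L]] <- rec
        next
      }
      pres <- setNames(lapply(names(aln$rows), function(r) {
        score_alu_presence(aln$rows[[r]], consensus, scheme,
                           threshold_fraction)
      }), names(aln$rows))
      pattern <- setNames(rep(FALSE, 4), names(GENOME_IDS))
      for (r in names(pres)) pattern[r] <- pres[[r]]$present
      if (!any(pattern)) {
        rec$status <- "no_presence_call"
        rec_rows[[length(rec_rows) + 1L]] <- rec
        next
      }
      rec$status <- "categorized"
      rec$category <- assign_category(unname(pattern))
      rec$set_number <- set_number(rec$category, g)
      rec$pattern <- paste(ifelse(pattern, "1", "0"), collapse = "")
      rec_rows[[length(rec_rows) + 1L]] <- rec
      details[[locus$locus_id]] <- list(alignment = aln, presence = pres,
                                        pattern = pattern)
    }
    if (verbose) message("ascertained from ", g, ": ",
                         sum(vapply(rec_rows, function(r)
                           identical(r$genome, g) &&
                             identical(r$status, "categorized"),
                           logical(1))), " candidates")
  }

  records <- if (length(rec_rows))
    do.call(rbind, lapply(rec_rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  else stop("no candidate loci found in input")

  cand <- records[records$status == "categorized", , drop = FALSE]
  dd <- dedupe_candidates(cand, overlap_tolerance)
  uniq <- dd$unique

  ## inspect every unique call
  verdicts <- character(nrow(uniq)); reasons <- character(nrow(uniq))
  pp <- logical(nrow(uniq)); subfams <- character(nrow(uniq))
  for (k in seq_len(nrow(uniq))) {
    d <- details[[uniq$locus_id[k]]]
    outc <- classify_inspection(d$alignment, d$pattern, consensus, scheme,
                                library = library, presence = d$presence)
    verdicts[k] <- outc$verdict; reasons[k] <- outc$other_reason
    pp[k] <- isTRUE(outc$precise_parallel)
    subfams[k] <- if (!is.null(outc$subfamily))
      paste(stats::na.omit(unique(unlist(outc$subfamily))), collapse = ",")
    else NA_character_
  }
  uniq$verdict <- verdicts; uniq$other_reason <- reasons
  uniq$precise_parallel <- pp; uniq$subfamilies <- subfams

  summary <- summarize(uniq)
  structure(list(records = records, unique = uniq, dedup = dd,
                 summary = summary,
                 n_candidates = nrow(cand), truth = dat$truth),
            class = "alu_pipeline_result")
}

#' @export
print.alu_pipeline_result <- function(x, ...) {
  cat(sprintf("Alu categorization pipeline: %d candidates, %d unique calls\n",
              x$n_candidates, nrow(x$unique)))
  print(x$summary)
  invisible(x)
}

#' Compare pipeline output against simulator ground truth
#'
#' Joins the pipeline's unique calls with the truth table by contig and
#' computes: the fraction of ascertained loci passing the length filter,
#' pattern/category accuracy over unique calls, the verdict vs event-type
#' confusion matrix (expected mapping: clean_shared to shared,
#' near_parallel to near_parallel, n_run/truncated/present_in_all to
#' other), its diagonal rate, and the number of clean_shared loci
#' miscalled near-parallel.
#'
#' @param result An `alu_pipeline_result`.
#' @param truth Truth data frame (default: the one carried by `result`).
#' @return List with `filter_pass_rate`, `pattern_accuracy`,
#'   `category_accuracy`, `confusion`, `diagonal_rate`,
#'   `np_from_clean`, `n_eval`.
#' @export
compare_to_truth <- function(result, truth = result$truth) {
  stopifnot(inherits(result, "alu_pipeline_result"), !is.null(truth))
  recs <- result$records
  asc <- recs[recs$status %in% c("categorized", "length_filtered"), ,
              drop = FALSE]
  filter_pass_rate <- mean(asc$passed_filter[!is.na(asc$passed_filter)])

  uniq <- result$unique
  m <- match(uniq$contig, truth$locus_id)
  tru <- truth[m, , drop = FALSE]
  truth_pattern <- paste0(tru$present_C + 0, tru$present_M + 0,
                          tru$present_O + 0, tru$present_S + 0)
  pattern_accuracy <- mean(uniq$pattern == truth_pattern)
  category_accuracy <- mean(uniq$category == tru$true_category)

  expected_verdict <- c(clean_shared = "shared",
                        near_parallel = "near_parallel",
                        n_run = "other", truncated = "other",
                        present_in_all = "other")
  ## one representative (lowest set number) per truth locus
  first <- !duplicated(uniq$contig)
  ev <- tru$event_type[first]
  vd <- uniq$verdict[first]
  keep <- ev %in% names(expected_verdict)
  confusion <- table(event = ev[keep], verdict = vd[keep])
  diagonal_rate <- mean(expected_verdict[ev[keep]] == vd[keep])
  np_from_clean <- sum(ev[keep] == "clean_shared" &
                         vd[keep] == "near_parallel")
  list(filter_pass_rate = filter_pass_rate,
       pattern_accuracy = pattern_accuracy,
       category_accuracy = category_accuracy,
       confusion = confusion, diagonal_rate = diagonal_rate,
       np_from_clean = np_from_clean, n_eval = sum(keep))
}
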