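## ---------------------------------------------------------------------------
## Synthetic five-genome cohort simulator: four ingroup genomes + one outgroup,
## one contig per locus, with Alu insertions planted under configurable
## category proportions, per-lineage substitution decay and corruption events
## (near-parallel insertions, N-runs, truncations, fragmented "present in
## all" rows). Emits FASTA genomes, RepeatMasker .out annotations, PSL anchor
## hits and a ground-truth table.
## ---------------------------------------------------------------------------

# 290 bp mock AluS-style base consensus. This is a synthetic stand-in, not a
# Repbase sequence: subfamily discrimination only needs a shared backbone
# with fixed diagnostic sites, not real Alu content.
.MOCK_CONSENSUS <- paste0(
  "ACACACGGACTGGATAACGGACTCAATTCAAATGGACGGTCAACTCAATACTCGCATCAGCCGTGTGGAC",
  "AAAACATTAATAACGGGCGACTGGTAGACTACTACAAGACGCTGTCATAACAGTTTGCGATCCGTAAATC",
  "CGGTCATCGAGCGATGATATCTACCCTCCAGTAGTCTTCTTGATACCACGGGGGACAGTCAGACTCTGCG",
  "ATCCCGCGCGCAGCACGAAAGGTCGAAGCCCTGCAGAGGATACAAGTCAGACCCCTGTCGAAGTAGGCAC",
  "ACATCAGATG")

## Deterministic transversion at fixed sites: A<->C, G<->T.
.subst_sites <- function(seq, sites) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  chars[sites] <- flip[chars[sites]]
  paste(chars, collapse = "")
}

#' Bundled mock Alu subfamily consensus library
#'
#' Four synthetic 290 bp "consensus" sequences (AluSc, AluTa7, AluTa10,
#' AluTa15) sharing a common backbone and differing at 8-9 fixed diagnostic
#' sites, so subfamily discrimination and precise-parallel logic can be
#' exercised without redistributing any real repeat-library content. Users
#' working with real genomes can supply genuine consensus sequences instead.
#'
#' @return Named character vector of four 290 bp sequences.
#' @export
default_subfamily_library <- function() {
  sc   <- .MOCK_CONSENSUS
  ta7  <- .subst_sites(sc, c(20, 60, 100, 140, 180, 220, 255, 275))
  ta10 <- .subst_sites(sc, c(35, 75, 115, 155, 195, 235, 265, 285))
  ta15 <- .subst_sites(sc, c(35, 75, 115, 155, 50, 90, 200, 250, 280))
  c(AluSc = sc, AluTa7 = ta7, AluTa10 = ta10, AluTa15 = ta15)
}

#' Default category weights for the simulator
#'
#' Probabilities over the fifteen presence/absence categories plus
#' `"none"` (a locus whose insertion is private to the outgroup and absent
#' from all four ingroup genomes). The ten multi-genome categories take 70%
#' of the mass, split in proportion to their observed unique-call
#' frequencies in the source comparative study; loci shared by all four
#' ingroup genomes (CMOS) take 15%, lineage-private loci 3.25% each, and
#' outgroup-private loci 2%.
#'
#' @return Named numeric vector over the 15 category labels and `"none"`,
#'   summing to 1.
#' @export
default_category_weights <- function() {
  uc <- c(CM = 132, CO = 73, CS = 411, MO = 223, MS = 202, OS = 165,
          CMO = 192, CMS = 238, COS = 286, MOS = 159)
  w <- setNames(numeric(16), c(CATEGORY_LEVELS, "none"))
  w[names(uc)] <- 0.70 * uc / sum(uc)
  w["CMOS"] <- 0.15
  w[c("C", "M", "O", "S")] <- 0.0325
  w["none"] <- 0.02
  w
}

#' Convert a category label to a presence pattern and back
#'
#' Patterns are ordered logical 4-vectors in (capuchin, marmoset,
#' owl monkey, squirrel monkey) = (C, M, O, S) order.
#'
#' @param category One of the 15 category labels.
#' @return `category_to_pattern`: named logical vector of length 4.
#' @export
category_to_pattern <- function(category) {
  stopifnot(category %in% CATEGORY_LEVELS)
  letters4 <- unname(GENOME_IDS)
  setNames(letters4 %in% strsplit(category, "", fixed = TRUE)[[1]],
           names(GENOME_IDS))
}

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulate_cohort()].
#'
#' @param seed Integer RNG seed; the same seed and configuration produce
#'   byte-identical outputs.
#' @param n_loci Number of loci to simulate (one contig per locus in every
#'   genome).
#' @param backbone_length Length in bp of the shared unique backbone per
#'   locus region (default 3000).
#' @param flank_unique_length Guaranteed unique flank on each side of the
#'   planted insertion, in bp; must be at least 600 so that flank
#'   extraction is never starved (default 700).
#' @param category_weights Probabilities over the 15 category labels plus
#'   `"none"` (outgroup-private); must sum to 1.
#' @param tsd_length_range Integer `[min, max]` target-site-duplication
#'   length in bp (default `c(8, 16)`).
#' @param a_tail_length_range Integer `[min, max]` poly-A tail length in bp
#'   (default `c(10, 40)`).
#' @param per_lineage_divergence Independent per-site substitution
#'   probability applied to each lineage after insertion planting
#'   (default 0.02, roughly emulating ~20 My of drift).
#' @param np_event_rate Fraction of loci converted to near-parallel
#'   insertion pairs (second carrier receives a different-subfamily element
#'   at a nearby but distinct position with its own TSD).
#' @param n_run_rate Fraction of loci receiving an N-run in one genome.
#' @param truncation_rate Fraction of loci with one genome's contig
#'   truncated through the locus region.
#' @param present_in_all_rate Fraction of loci in which one nominally
#'   absent genome retains fragments of the element (internal deletion),
#'   so that presence scoring calls it absent while inspection should
#'   recognise the element in all genomes.
#' @param np_offset_range Integer `[min, max]` offset in bp between the two
#'   insertions of a near-parallel pair (default `c(10, 60)`).
#' @param n_run_length Length of planted N-runs in bp (default 150).
#' @param subfamily_library Named character vector of consensus sequences
#'   (default [default_subfamily_library()]).
#' @return An object of class `alu_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_loci = 100L,
                              backbone_length = 3000L,
                              flank_unique_length = 700L,
                              category_weights = default_category_weights(),
                              tsd_length_range = c(8L, 16L),
                              a_tail_length_range = c(10L, 40L),
                              per_lineage_divergence = 0.02,
                              np_event_rate = 0,
                              n_run_rate = 0,
                              truncation_rate = 0,
                              present_in_all_rate = 0,
                              np_offset_range = c(10L, 60L),
                              n_run_length = 150L,
                              subfamily_library = default_subfamily_library()) {
  if (!is.numeric(category_weights) || is.null(names(category_weights)))
    stop("category_weights must be a named numeric vector")
  full <- setNames(numeric(16), c(CATEGORY_LEVELS, "none"))
  bad <- setdiff(names(category_weights), names(full))
  if (length(bad))
    stop("unknown category in weights: ", paste(bad, collapse = ", "))
  full[names(category_weights)] <- category_weights
  if (any(full < 0) || abs(sum(full) - 1) > 1e-9)
    stop("category_weights must be non-negative and sum to 1")
  chk_range <- function(r, what) {
    if (length(r) != 2 || any(r < 1) || r[1] > r[2])
      stop(what, " must be a positive [min, max] pair")
    as.integer(r)
  }
  tsd_length_range <- chk_range(tsd_length_range, "tsd_length_range")
  a_tail_length_range <- chk_range(a_tail_length_range, "a_tail_length_range")
  np_offset_range <- chk_range(np_offset_range, "np_offset_range")
  if (flank_unique_length < 600)
    stop("flank_unique_length must be >= 600 (the alignment stage needs ",
         "600 bp flanks)")
  rates <- c(np_event_rate, n_run_rate, truncation_rate, present_in_all_rate)
  if (any(rates < 0) || sum(rates) > 1)
    stop("corruption rates must be non-negative and sum to at most 1")
  if (per_lineage_divergence < 0 || per_lineage_divergence > 0.5)
    stop("per_lineage_divergence must be in [0, 0.5]")
  if (!length(subfamily_library) || is.null(names(subfamily_library)))
    stop("subfamily_library must be a non-empty named character vector")
  if (backbone_length < 2 * flank_unique_length + 400)
    stop("backbone_length too short for the configured flanks")
  structure(list(
    seed = as.integer(seed), n_loci = as.integer(n_loci),
    backbone_length = as.integer(backbone_length),
    flank_unique_length = as.integer(flank_unique_length),
    category_weights = full,
    tsd_length_range = tsd_length_range,
    a_tail_length_range = a_tail_length_range,
    per_lineage_divergence = per_lineage_divergence,
    np_event_rate = np_event_rate, n_run_rate = n_run_rate,
    truncation_rate = truncation_rate,
    present_in_all_rate = present_in_all_rate,
    np_offset_range = np_offset_range,
    n_run_length = as.integer(n_run_length),
    subfamily_library = subfamily_library
  ), class = "alu_sim_config")
}

#' Plant an Alu insertion with TSD and poly-A tail into a backbone
#'
#' Reproduces the retrotransposition signature: the `tsd_len` backbone bases
#' at `[position, position + tsd_len)` (0-based) are duplicated so that one
#' copy precedes the element and the second copy follows the poly-A tail.
#' The result is
#' `backbone[0:(position+tsd_len)] + alu + A^a_tail_len + backbone[position:]`
#' with total length `nchar(backbone) + nchar(alu) + a_tail_len + tsd_len`.
#'
#' @param backbone Host sequence.
#' @param position 0-based insertion point; must satisfy
#'   `tsd_len < position < nchar(backbone)` and
#'   `position + tsd_len <= nchar(backbone)`.
#' @param alu Element sequence to insert.
#' @param tsd_len Target-site duplication length (>= 1).
#' @param a_tail_len Poly-A tail length (>= 0).
#' @return The modified sequence (character scalar).
#' @examples
#' plant_insertion("ACGTACGTAC", 5, "TTTT", 2, 0)  # "ACGTACGTTTTCGTAC"
#' @export
plant_insertion <- function(backbone, position, alu, tsd_len, a_tail_len = 0) {
  n <- nchar(backbone)
  if (tsd_len < 1) stop("tsd_len must be >= 1")
  if (a_tail_len < 0) stop("a_tail_len must be >= 0")
  if (position <= 0 || position >= n)
    stop("position must satisfy 0 < position < length(backbone)")
  if (position + tsd_len > n)
    stop("position too close to the sequence end for tsd_len")
  if (position <= tsd_len)
    stop("duplication window would underflow the sequence start")
  paste0(substr(backbone, 1, position + tsd_len),
         alu, strrep("A", a_tail_len),
         substr(backbone, position + 1, n))
}

## ---------------------------------------------------------------------------
## Truth drawing. The RNG contract (relied on by replay oracles) is:
## after set.seed(seed), the first n_loci runif draws pick the category by
## cumulative-weight bins over names(category_weights) in configuration
## order, and the next n_loci runif draws pick the corruption event by the
## bins [0, np), [np, np+n_run), [.., +truncation), [.., +present_in_all),
## remainder clean_shared. Deterministic eligibility downgrades follow
## (no further draws): "none" loci become outgroup_shared; near_parallel
## needs >= 2 carriers, present_in_all needs >= 1 absent ingroup genome,
## otherwise the event degrades to clean_shared.
## ---------------------------------------------------------------------------
.draw_truth <- function(config) {
  n <- config$n_loci
  w <- config$category_weights
  cuts <- cumsum(w)
  u_cat <- runif(n)
  category <- names(w)[findInterval(u_cat, c(0, cuts),
                                    rightmost.closed = TRUE)]
  r <- c(config$np_event_rate, config$n_run_rate,
         config$truncation_rate, config$present_in_all_rate)
  ev_cuts <- cumsum(r)
  u_ev <- runif(n)
  idx <- findInterval(u_ev, c(0, ev_cuts), rightmost.closed = TRUE)
  event <- c("near_parallel", "n_run", "truncated",
             "present_in_all", "clean_shared")[idx]
  n_carriers <- nchar(category)
  n_carriers[category == "none"] <- 0L
  event[category == "none"] <- "outgroup_shared"
  event[event == "near_parallel" & n_carriers < 2] <- "clean_shared"
  event[event == "present_in_all" &
          (category == "CMOS" | n_carriers < 1)] <- "clean_shared"
  data.frame(locus_id = sprintf("locus%04d", seq_len(n)),
             true_category = category, event_type = event,
             stringsAsFactors = FALSE)
}

#' Draw the per-locus category and corruption-event truth table
#'
#' Performs only the first-pass random draws of the simulator (category and
#' event per locus), without constructing sequences. This is the documented
#' RNG contract: after `set.seed(seed)`, the first `n_loci` uniform draws
#' select categories by cumulative-weight bins (in the order of
#' `names(category_weights)`) and the next `n_loci` draws select corruption
#' events by the bins np / n_run / truncation / present_in_all / clean;
#' deterministic eligibility downgrades follow (loci in category `"none"`
#' become `outgroup_shared`; `near_parallel` requires at least two
#' carriers; `present_in_all` requires at least one absent ingroup genome).
#'
#' @param config An [simulation_config()].
#' @return Data frame with `locus_id`, `true_category`, `event_type`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "alu_sim_config"))
  set.seed(config$seed)
  .draw_truth(config)
}

## uniform integer in [lo, hi] from one runif draw
.runif_int <- function(lo, hi) {
  as.integer(pmin(floor(runif(1, lo, hi + 1)), hi))
}

## ---------------------------------------------------------------------------
## Segment maps. A genome's locus sequence is a concatenation of segments,
## each a window into a coordinate "space": the shared backbone ("bb") or an
## insertion event space ("ins1", "ins2"). Orthology blocks between two
## genomes are the intersections of their same-space segments; this is what
## the PSL writer emits as BLAT-style anchor hits.
## ---------------------------------------------------------------------------
.seg <- function(space, ss, se, gs) {
  data.frame(space = space, ss = ss, se = se, gs = gs,
             stringsAsFactors = FALSE)
}

## blocks between two segment maps, in genome coordinates of a and b
.map_blocks <- function(segs_a, segs_b) {
  out <- list()
  for (ia in seq_len(nrow(segs_a))) {
    sa <- segs_a[ia, ]
    sb_all <- segs_b[segs_b$space == sa$space, , drop = FALSE]
    for (ib in seq_len(nrow(sb_all))) {
      sb <- sb_all[ib, ]
      lo <- max(sa$ss, sb$ss); hi <- min(sa$se, sb$se)
      if (hi > lo) {
        out[[length(out) + 1L]] <- c(
          a = sa$gs + (lo - sa$ss), b = sb$gs + (lo - sb$ss), len = hi - lo)
      }
    }
  }
  if (!length(out))
    return(data.frame(a = integer(0), b = integer(0), len = integer(0)))
  df <- as.data.frame(do.call(rbind, out))
  df <- df[order(df$a), , drop = FALSE]
  ## merge blocks contiguous in both coordinates
  keep <- list(); cur <- df[1, ]
  for (k in seq_len(nrow(df))[-1]) {
    nxt <- df[k, ]
    if (nxt$a == cur$a + cur$len && nxt$b == cur$b + cur$len) {
      cur$len <- cur$len + nxt$len
    } else {
      keep[[length(keep) + 1L]] <- cur; cur <- nxt
    }
  }
  keep[[length(keep) + 1L]] <- cur
  do.call(rbind, keep)
}

## clip blocks to a genome-coordinate window on side a and drop empties
.clip_blocks_a <- function(blocks, lo, hi) {
  if (!nrow(blocks)) return(blocks)
  s <- pmax(blocks$a, lo); e <- pmin(blocks$a + blocks$len, hi)
  sel <- e > s
  data.frame(a = s[sel] ,
             b = blocks$b[sel] + (s[sel] - blocks$a[sel]),
             len = (e - s)[sel])
}

.clip_blocks_b <- function(blocks, lo, hi) {
  if (!nrow(blocks)) return(blocks)
  s <- pmax(blocks$b, lo); e <- pmin(blocks$b + blocks$len, hi)
  sel <- e > s
  data.frame(a = blocks$a[sel] + (s[sel] - blocks$b[sel]),
             b = s[sel], len = (e - s)[sel])
}

#' Simulate a five-genome Alu insertion cohort
#'
#' Generates four ingroup genomes plus one outgroup (one contig per locus),
#' plants Alu insertions according to the configured category weights,
#' applies corruption events and per-lineage substitution decay, and
#' produces RepeatMasker-style `.out` annotations, BLAT-style PSL anchor
#' hits for every (ascertainment genome, other genome) pair, and a
#' ground-truth table. With `out_dir` set, everything is written to disk
#' (`genomes/*.fa`, `annotations/*.out`, `anchors/*_vs_*.psl`,
#' `truth.tsv`); outputs are byte-identical for identical seed + config.
#'
#' @param config An [simulation_config()].
#' @param out_dir Output directory (created if needed), or `NULL` to keep
#'   everything in memory.
#' @return An object of class `alu_cohort`: list with `config`, `genomes`
#'   (named list of named contig vectors), `annotations` (data frame),
#'   `psl` (named list of data frames, one per genome pair), `truth`
#'   (data frame) and `dir` (the output directory or `NULL`).
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "alu_sim_config"))
  set.seed(config$seed)
  truth0 <- .draw_truth(config)

  lib <- config$subfamily_library
  B <- config$backbone_length
  gnames <- c(names(GENOME_IDS), OUTGROUP_ID)
  genomes <- setNames(lapply(gnames, function(g) character(0)), gnames)
  ann_rows <- list()
  psl_rows <- list()   # keyed "src|tgt"
  truth_extra <- list()

  for (i in seq_len(config$n_loci)) {
    contig <- truth0$locus_id[i]
    category <- truth0$true_category[i]
    event <- truth0$event_type[i]
    pattern <- if (category == "none") {
      setNames(rep(FALSE, 4), names(GENOME_IDS))
    } else category_to_pattern(category)
    carriers <- names(pattern)[pattern]

    backbone <- rand_dna(B)
    pos <- B %/% 2L + .runif_int(-100L, 100L)
    tsd_len <- .runif_int(config$tsd_length_range[1], config$tsd_length_range[2])
    a_tail <- .runif_int(config$a_tail_length_range[1],
                         config$a_tail_length_range[2])
    subfam_i <- .runif_int(1L, length(lib))
    subfam <- names(lib)[subfam_i]
    tsd_seq <- substr(backbone, pos + 1, pos + tsd_len)
    ins_seq <- paste0(lib[[subfam_i]], strrep("A", a_tail), tsd_seq)
    ins_len <- nchar(ins_seq)
    alu_len <- nchar(lib[[subfam_i]])

    ## event details (draws happen for every eligible event type)
    np_carrier <- np_pos <- np_subfam <- np_tsd_len <- np_a_tail <- NULL
    np_ins_seq <- NULL
    if (event == "near_parallel") {
      np_carrier <- carriers[2]
      off <- .runif_int(config$np_offset_range[1], config$np_offset_range[2])
      sgn <- if (runif(1) < 0.5) -1L else 1L
      np_pos <- pos + sgn * off
      others <- setdiff(seq_along(lib), subfam_i)
      np_subfam_i <- others[.runif_int(1L, length(others))]
      np_subfam <- names(lib)[np_subfam_i]
      np_tsd_len <- .runif_int(config$tsd_length_range[1],
                               config$tsd_length_range[2])
      np_a_tail <- .runif_int(config$a_tail_length_range[1],
                              config$a_tail_length_range[2])
      np_tsd_seq <- substr(backbone, np_pos + 1, np_pos + np_tsd_len)
      np_ins_seq <- paste0(lib[[np_subfam_i]], strrep("A", np_a_tail),
                           np_tsd_seq)
    }
    corrupt_genome <- NULL
    if (event %in% c("n_run", "truncated")) {
      corrupt_genome <- names(GENOME_IDS)[.runif_int(1L, 4L)]
      if (event == "truncated" && length(carriers) &&
          corrupt_genome == carriers[1]) {
        ## never truncate the lowest-order carrier, so the locus always
        ## remains ascertainable and flows to inspection
        pool <- setdiff(names(GENOME_IDS), carriers[1])
        corrupt_genome <- pool[1L + (match(corrupt_genome,
                                           names(GENOME_IDS)) %% 3L)]
      }
    }
    frag_genome <- NULL
    if (event == "present_in_all") {
      frag_genome <- setdiff(names(GENOME_IDS), carriers)[1]
    }

    ## assemble per-genome sequence, segment map, annotations
    locus_seq <- list(); locus_segs <- list()
    for (g in gnames) {
      is_carrier <- g %in% carriers
      is_np <- !is.null(np_carrier) && identical(g, np_carrier)
      is_frag <- !is.null(frag_genome) && identical(g, frag_genome)
      is_out_carrier <- (g == OUTGROUP_ID && category == "none")
      protect <- integer(0)
      if (is_np) {
        gs <- np_pos + np_tsd_len
        seq <- paste0(substr(backbone, 1, gs), np_ins_seq,
                      substr(backbone, np_pos + 1, B))
        segs <- rbind(.seg("bb", 0L, gs, 0L),
                      .seg("ins2", 0L, nchar(np_ins_seq), gs),
                      .seg("bb", gs, B, gs + nchar(np_ins_seq)))
        protect <- c(seq(np_pos + 1, gs),
                     seq(gs + nchar(np_ins_seq) - np_tsd_len + 1,
                         gs + nchar(np_ins_seq)))
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          genome_id = g, contig = contig, qbegin = gs + 1,
          qend = gs + nchar(lib[[np_subfam]]) + np_a_tail, strand = "+",
          repeat_name = np_subfam, repeat_class = "SINE/Alu",
          rbegin = 1L, rend = nchar(lib[[np_subfam]]), rleft = 0L,
          stringsAsFactors = FALSE)
      } else if (is_carrier || is_out_carrier) {
        gs <- pos + tsd_len
        seq <- paste0(substr(backbone, 1, gs), ins_seq,
                      substr(backbone, pos + 1, B))
        segs <- rbind(.seg("bb", 0L, gs, 0L),
                      .seg("ins1", 0L, ins_len, gs),
                      .seg("bb", gs, B, gs + ins_len))
        protect <- c(seq(pos + 1, gs),
                     seq(gs + ins_len - tsd_len + 1, gs + ins_len))
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          genome_id = g, contig = contig, qbegin = gs + 1,
          qend = gs + alu_len + a_tail, strand = "+",
          repeat_name = subfam, repeat_class = "SINE/Alu",
          rbegin = 1L, rend = alu_len, rleft = 0L,
          stringsAsFactors = FALSE)
      } else if (is_frag) {
        ## internal deletion of consensus bases [60, 260): fragments of the
        ## element remain (enough k-mer content for inspection to notice)
        ## but full-length ascertainment and presence scoring both miss it
        gs <- pos + tsd_len
        keep5 <- 60L; del_to <- 260L
        frag_seq <- paste0(substr(ins_seq, 1, keep5),
                           substr(ins_seq, del_to + 1, ins_len))
        seq <- paste0(substr(backbone, 1, gs), frag_seq,
                      substr(backbone, pos + 1, B))
        segs <- rbind(.seg("bb", 0L, gs, 0L),
                      .seg("ins1", 0L, keep5, gs),
                      .seg("ins1", del_to, ins_len, gs + keep5),
                      .seg("bb", gs, B, gs + nchar(frag_seq)))
        protect <- c(seq(pos + 1, gs),
                     seq(gs + nchar(frag_seq) - tsd_len + 1,
                         gs + nchar(frag_seq)))
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          genome_id = g, contig = contig, qbegin = gs + 1,
          qend = gs + keep5, strand = "+",
          repeat_name = subfam, repeat_class = "SINE/Alu",
          rbegin = 1L, rend = keep5, rleft = alu_len - keep5,
          stringsAsFactors = FALSE)
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          genome_id = g, contig = contig, qbegin = gs + keep5 + 1,
          qend = gs + keep5 + (alu_len - del_to) + a_tail, strand = "+",
          repeat_name = subfam, repeat_class = "SINE/Alu",
          rbegin = del_to + 1L, rend = alu_len, rleft = 0L,
          stringsAsFactors = FALSE)
      } else {
        seq <- backbone
        segs <- .seg("bb", 0L, B, 0L)
      }
      seq <- mutate_seq(seq, config$per_lineage_divergence, protect)
      if (!is.null(corrupt_genome) && identical(g, corrupt_genome) &&
          event == "n_run") {
        a <- pos - 400L
        substr(seq, a + 1, a + config$n_run_length) <-
          strrep("N", config$n_run_length)
      }
      if (!is.null(corrupt_genome) && identical(g, corrupt_genome) &&
          event == "truncated") {
        cut <- if (g %in% carriers) pos + tsd_len + ins_len + 20L else pos + 20L
        seq <- substr(seq, 1, cut)
        segs$se <- pmin(segs$se, segs$ss + pmax(0L, cut - segs$gs))
        segs <- segs[segs$se > segs$ss, , drop = FALSE]
      }
      locus_seq[[g]] <- seq
      locus_segs[[g]] <- segs
    }

    for (g in gnames)
      genomes[[g]][contig] <- locus_seq[[g]]

    ## PSL anchors: one query per ascertainable full-length element
    asc <- list()
    for (g in names(GENOME_IDS)) {
      if (g %in% carriers && !(identical(g, np_carrier))) {
        asc[[length(asc) + 1L]] <- list(g = g, gs = pos + tsd_len,
                                        ge = pos + tsd_len + alu_len + a_tail)
      } else if (identical(g, np_carrier)) {
        asc[[length(asc) + 1L]] <- list(
          g = g, gs = np_pos + np_tsd_len,
          ge = np_pos + np_tsd_len + nchar(lib[[np_subfam]]) + np_a_tail)
      }
    }
    for (a in asc) {
      q0 <- a$gs - 600L; q1 <- a$ge + 600L
      if (q0 < 0 || q1 > nchar(locus_seq[[a$g]])) next  # not ascertainable
      qname <- sprintf("%s:%s:%d-%d", a$g, contig, q0, q1)
      qsize <- q1 - q0
      for (tgt in setdiff(gnames, a$g)) {
        blocks <- .map_blocks(locus_segs[[a$g]], locus_segs[[tgt]])
        blocks <- .clip_blocks_a(blocks, q0, q1)
        if (!nrow(blocks)) next
        key <- paste(a$g, tgt, sep = "|")
        row <- data.frame(
          matches = sum(blocks$len), misMatches = 0L, repMatches = 0L,
          nCount = 0L, qNumInsert = 0L, qBaseInsert = 0L,
          tNumInsert = 0L, tBaseInsert = 0L, strand = "+",
          qName = qname, qSize = qsize,
          qStart = min(blocks$a) - q0, qEnd = max(blocks$a + blocks$len) - q0,
          tName = contig, tSize = nchar(locus_seq[[tgt]]),
          tStart = min(blocks$b), tEnd = max(blocks$b + blocks$len),
          blockCount = nrow(blocks),
          blockSizes = paste0(paste(blocks$len, collapse = ","), ","),
          qStarts = paste0(paste(blocks$a - q0, collapse = ","), ","),
          tStarts = paste0(paste(blocks$b, collapse = ","), ","),
          stringsAsFactors = FALSE)
        psl_rows[[key]] <- c(psl_rows[[key]], list(row))
      }
    }

    ## truth extras
    ins_start <- setNames(rep(NA_integer_, 4), names(GENOME_IDS))
    sub_by_g <- setNames(rep(NA_character_, 4), names(GENOME_IDS))
    for (g in carriers) {
      if (identical(g, np_carrier)) {
        ins_start[g] <- np_pos + np_tsd_len; sub_by_g[g] <- np_subfam
      } else {
        ins_start[g] <- pos + tsd_len; sub_by_g[g] <- subfam
      }
    }
    truth_extra[[i]] <- cbind(
      data.frame(present_C = pattern[["capuchin"]],
                 present_M = pattern[["marmoset"]],
                 present_O = pattern[["owl_monkey"]],
                 present_S = pattern[["squirrel_monkey"]],
                 tsd_sequence = tsd_seq,
                 planted_position = pos + tsd_len,
                 stringsAsFactors = FALSE),
      setNames(as.data.frame(as.list(ins_start)),
               paste0("ins_start_", unname(GENOME_IDS))),
      setNames(as.data.frame(as.list(sub_by_g), stringsAsFactors = FALSE),
               paste0("subfamily_", unname(GENOME_IDS))))
  }

  truth <- cbind(truth0, do.call(rbind, truth_extra))
  annotations <- do.call(rbind, ann_rows)
  psl <- lapply(psl_rows, function(rows) do.call(rbind, rows))

  cohort <- structure(list(config = config, genomes = genomes,
                           annotations = annotations, psl = psl,
                           truth = truth, dir = out_dir),
                      class = "alu_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.alu_cohort <- function(x, ...) {
  cat(sprintf("Simulated Alu cohort: %d loci x %d genomes (seed %d)\n",
              x$config$n_loci, length(x$genomes), x$config$seed))
  cat("events:\n")
  print(table(x$truth$event_type))
  if (!is.null(x$dir)) cat("written to:", x$dir, "\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes `genomes/<genome>.fa`, `annotations/<genome>.out` (RepeatMasker
#' .out layout), `anchors/<src>_vs_<tgt>.psl` and `truth.tsv`.
#'
#' @param cohort An `alu_cohort` from [simulate_cohort()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "alu_cohort"))
  for (d in file.path(out_dir, c("genomes", "annotations", "anchors")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (g in names(cohort$genomes)) {
    xs <- Biostrings::DNAStringSet(cohort$genomes[[g]])
    Biostrings::writeXStringSet(xs, file.path(out_dir, "genomes",
                                              paste0(g, ".fa")))
    ann <- cohort$annotations[cohort$annotations$genome_id == g, ,
                              drop = FALSE]
    write_repeat_annotations(ann, file.path(out_dir, "annotations",
                                            paste0(g, ".out")))
  }
  for (key in names(cohort$psl)) {
    pair <- strsplit(key, "|", fixed = TRUE)[[1]]
    write_psl(cohort$psl[[key]],
              file.path(out_dir, "anchors",
                        paste0(pair[1], "_vs_", pair[2], ".psl")))
  }
  write.table(cohort$truth, file.path(out_dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
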