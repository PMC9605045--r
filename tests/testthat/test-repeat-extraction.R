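hdr3 <- c("header line 1", "header line 2", "")

out_line <- function(contig, qb, qe, strand = "+", name = "AluSc",
                     cls = "SINE/Alu", cons = "1 290 (0)") {
  sprintf("2000 1.0 0.0 0.0 %s %d %d (0) %s %s %s %s 1",
          contig, qb, qe, strand, name, cls, cons)
}

test_that("a header-only .out file parses to an empty table", {
  expect_equal(nrow(parse_repeat_annotations(hdr3, "g")), 0)
})

test_that(".out genomic coordinates normalize to 0-based half-open", {
  ann <- parse_repeat_annotations(c(hdr3, out_line("chr1", 101, 400)), "g")
  expect_equal(ann$start, 100)
  expect_equal(ann$end, 400)
  expect_equal(ann$end - ann$start, 300)
  expect_equal(ann$consensus_offset, 0)
})

test_that("minus-strand consensus coordinates normalize to a 5' offset", {
  ## C-strand consensus fields are (left) end begin: "(0) 300 20" means the
  ## match spans consensus positions 20..300 (1-based), i.e. 19 bases of
  ## consensus are missing 5' of the match
  ann <- parse_repeat_annotations(
    c(hdr3, out_line("chr1", 101, 400, strand = "C", cons = "(0) 300 20")),
    "g")
  expect_equal(ann$strand, "-")
  expect_equal(ann$consensus_offset, 19)
})

test_that("malformed .out records fail with the offending line number", {
  expect_error(parse_repeat_annotations(c(hdr3, "too few fields"), "g"),
               "line 4")
})

test_that("full-length selection applies inclusive boundaries", {
  ann <- parse_repeat_annotations(c(
    hdr3,
    out_line("c1", 101, 366),                    # length 266: too short
    out_line("c2", 101, 367, cons = "5 290 (0)"), # length 267, offset 4: keep
    out_line("c3", 101, 500, cons = "6 290 (0)"), # offset 5: too far in
    out_line("c4", 101, 500, cons = "1 290 (0)", name = "L1",
             cls = "LINE/L1")),                  # not Alu
    "g")
  kept <- select_full_length(ann)
  expect_equal(kept$contig, "c2")
})

test_that("full-length selection is idempotent and splits over concat", {
  ann <- parse_repeat_annotations(c(
    hdr3,
    out_line("c1", 101, 500),
    out_line("c2", 101, 320),
    out_line("c3", 101, 600, cons = "9 290 (0)")), "g")
  once <- select_full_length(ann)
  expect_identical(select_full_length(once), once)
  split <- rbind(select_full_length(ann[1:2, ]),
                 select_full_length(ann[3, , drop = FALSE]))
  expect_identical(once, split)
})

test_that("extraction returns flank + element + flank spans", {
  set.seed(21)
  contig <- rand_seq(2000)
  alu <- rand_seq(300)
  genome <- c(chrA = paste0(substr(contig, 1, 800), alu,
                            substr(contig, 801, 2000)))
  ann <- data.frame(genome_id = "g", contig = "chrA", start = 800,
                    end = 1100, strand = "+", repeat_name = "AluSc",
                    repeat_class = "SINE/Alu", consensus_offset = 0,
                    divergence_pct = 0, stringsAsFactors = FALSE)
  loc <- extract_locus_with_flanks(genome, ann)
  expect_equal(loc$status, "ok")
  expect_equal(nchar(loc$query), 1500)
  expect_identical(loc$sequence_alu, alu)
  expect_equal(nchar(loc$sequence_5flank), 600)
  expect_equal(nchar(loc$sequence_3flank), 600)
})

test_that("loci too close to a contig edge are rejected, not shortened", {
  genome <- c(chrA = rand_seq(1500))
  ann <- data.frame(genome_id = "g", contig = "chrA", start = 100,
                    end = 400, strand = "+", repeat_name = "AluSc",
                    repeat_class = "SINE/Alu", consensus_offset = 0,
                    divergence_pct = 0, stringsAsFactors = FALSE)
  expect_equal(extract_locus_with_flanks(genome, ann)$status, "edge_locus")
  ann$contig <- "nope"
  expect_error(extract_locus_with_flanks(genome, ann), "contig not found")
})

test_that("minus-strand loci come out in consensus orientation", {
  ## toy contig: 10 bp 5' flank, 6 bp element, 10 bp 3' flank
  contig <- "ACGTACGTTGGATCCAGGTTACAGTACCGG"
  genome <- c(c1 = contig)
  ann <- data.frame(genome_id = "g", contig = "c1", start = 10, end = 16,
                    strand = "-", repeat_name = "AluSc",
                    repeat_class = "SINE/Alu", consensus_offset = 0,
                    divergence_pct = 0, stringsAsFactors = FALSE)
  loc <- extract_locus_with_flanks(genome, ann, flank = 10)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_identical(loc$sequence_alu, rc(substr(contig, 11, 16)))
  expect_identical(loc$sequence_5flank, rc(substr(contig, 17, 26)))
  expect_identical(loc$sequence_3flank, rc(substr(contig, 1, 10)))
})

test_that("every planted full-length element is recovered from simulation", {
  cfg <- simulation_config(seed = 17, n_loci = 10,
                           per_lineage_divergence = 0)
  co <- simulate_cohort(cfg, file.path(tempdir(), "rec"))
  dat <- load_cohort_dir(file.path(tempdir(), "rec"))
  ig <- ingroup_genomes()
  for (letter in names(ig)) {
    g <- ig[[letter]]
    full <- select_full_length(dat$annotations[[g]])
    planted <- co$truth[[paste0("ins_start_", letter)]]
    want <- co$truth$locus_id[!is.na(planted)]
    expect_setequal(full$contig, want)
    for (k in seq_len(nrow(full))) {
      loc <- extract_locus_with_flanks(dat$genomes[[g]], full[k, ])
      expect_equal(loc$status, "ok")
      i <- match(loc$contig, co$truth$locus_id)
      expect_equal(loc$alu_start, planted[i])
    }
  }
})
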