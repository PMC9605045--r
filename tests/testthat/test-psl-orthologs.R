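psl_line <- function(qName, qSize, tName, tSize, sizes, qs, ts,
                     strand = "+") {
  j <- function(v) paste0(paste(v, collapse = ","), ",")
  nb <- length(sizes)
  paste(sum(sizes), 0, 0, 0, 0, 0, 0, 0, strand, qName, qSize,
        qs[1], qs[nb] + sizes[nb], tName, tSize, ts[1], ts[nb] + sizes[nb],
        nb, j(sizes), j(qs), j(ts), sep = "\t")
}

toy_locus <- function() {
  set.seed(33)
  contig <- rand_seq(2000)
  alu <- rand_seq(300)
  genome <- c(chrA = paste0(substr(contig, 1, 800), alu,
                            substr(contig, 801, 2000)))
  ann <- data.frame(genome_id = "capuchin", contig = "chrA", start = 800,
                    end = 1100, strand = "+", repeat_name = "AluSc",
                    repeat_class = "SINE/Alu", consensus_offset = 0,
                    divergence_pct = 0, stringsAsFactors = FALSE)
  extract_locus_with_flanks(genome, ann)
}

test_that("PSL parsing round-trips and validates block structure", {
  l1 <- psl_line("q1", 1500, "t1", 5000, c(600, 600), c(0, 900), c(100, 720))
  psl <- read_psl(c("psLayout version 3", "", l1))
  expect_equal(nrow(psl), 1)
  expect_equal(psl$block_sizes[[1]], c(600, 600))
  expect_equal(psl$tStart, 100)
  ## overlapping blocks are rejected
  bad <- psl_line("q1", 1500, "t1", 5000, c(600, 600), c(0, 500), c(100, 720))
  expect_error(read_psl(bad), "ascending")
  expect_error(read_psl("1 2 3"), "malformed PSL")
})

test_that("an insertion-sized query gap at the element means lineage specific", {
  loc <- toy_locus()
  ## both flanks anchor; query gap of 320 over the element, target gap 0
  hit <- read_psl(psl_line(loc$locus_id, 1500, "oc1", 9000,
                           c(590, 590), c(0, 910), c(1000, 1590)))
  res <- check_lineage_specific(loc, hit)
  expect_true(res$specific)
  expect_equal(res$status, "lineage_specific")
  expect_equal(res$gap, 320)
})

test_that("a gap-free full-cover hit means the outgroup shares the element", {
  loc <- toy_locus()
  hit <- read_psl(psl_line(loc$locus_id, 1500, "oc1", 9000,
                           1500, 0, 1000))
  res <- check_lineage_specific(loc, hit)
  expect_false(res$specific)
  expect_equal(res$status, "outgroup_present")
})

test_that("flanks hitting different contigs are unmappable", {
  loc <- toy_locus()
  hits <- read_psl(c(
    psl_line(loc$locus_id, 1500, "ocA", 9000, 600, 0, 1000),
    psl_line(loc$locus_id, 1500, "ocB", 9000, 600, 900, 2000)))
  expect_equal(check_lineage_specific(loc, hits)$status, "unmappable")
  none <- read_psl(character(0))
  expect_equal(check_lineage_specific(loc, none)$status, "unmappable")
  expect_true(is.na(check_lineage_specific(loc, none)$specific))
})

test_that("ortholog fetch spans intervening target insertions", {
  loc <- toy_locus()
  set.seed(8)
  target <- c(mc1 = rand_seq(9000))
  ## two colinear blocks separated by a 310 bp target-only gap
  hits <- list(marmoset = read_psl(psl_line(
    loc$locus_id, 1500, "mc1", 9000, c(750, 750), c(0, 750), c(2000, 3060))))
  orth <- fetch_orthologs(loc, list(marmoset = target), hits)
  expect_equal(nchar(orth$marmoset$sequence), 1500 + 310)
  expect_equal(orth$marmoset$start, 2000)
  ## a genome with no hit is reported missing
  orth2 <- fetch_orthologs(loc, list(marmoset = target),
                           list(marmoset = read_psl(character(0))))
  expect_null(orth2$marmoset)
})

test_that("best-hit selection is deterministic under ties", {
  loc <- toy_locus()
  set.seed(9)
  target <- c(aaa = rand_seq(5000), bbb = rand_seq(5000))
  hits <- list(marmoset = read_psl(c(
    psl_line(loc$locus_id, 1500, "bbb", 5000, 1500, 0, 1200),
    psl_line(loc$locus_id, 1500, "aaa", 5000, 1500, 0, 1200))))
  orth <- fetch_orthologs(loc, list(marmoset = target), hits)
  expect_equal(orth$marmoset$contig, "aaa")
})

test_that("four identical sequences align without gaps", {
  set.seed(14)
  s <- rand_seq(400)
  aln <- align_four_way(list(capuchin = s, marmoset = s,
                             owl_monkey = s, squirrel_monkey = s))
  expect_equal(aln$column_count, 400)
  expect_true(all(!grepl("-", aln$rows, fixed = TRUE)))
  expect_equal(length(aln$missing), 0)
})

test_that("a non-carrier row shows one contiguous insertion-sized gap", {
  set.seed(15)
  backbone <- rand_seq(1200)
  alu <- rand_seq(280)
  carrier <- plant_insertion(backbone, 600, alu, 10, 20)
  aln <- align_four_way(list(capuchin = carrier, marmoset = carrier,
                             owl_monkey = backbone, squirrel_monkey = carrier))
  expect_equal(aln$column_count, nchar(carrier))
  gaps <- gregexpr("-+", aln$rows[["owl_monkey"]])[[1]]
  ## essentially one insertion-sized block (tail bases matching backbone
  ## A's may shave a few columns off its edges)
  expect_gte(max(attr(gaps, "match.length")), 280)
  expect_equal(sum(attr(gaps, "match.length")), 280 + 20 + 10)
  ## ungapped rows are bit-identical to their inputs
  expect_identical(gsub("-", "", aln$rows[["owl_monkey"]]), backbone)
  expect_identical(gsub("-", "", aln$rows[["capuchin"]]), carrier)
})

test_that("substitutions alone do not open alignment gaps", {
  set.seed(16)
  s <- rand_seq(500)
  s2 <- s
  substr(s2, 250, 250) <- if (substr(s, 250, 250) == "A") "C" else "A"
  aln <- align_four_way(list(capuchin = s, marmoset = s2))
  expect_equal(aln$column_count, 500)
  expect_equal(aln$missing, c("owl_monkey", "squirrel_monkey"))
})

test_that("alignment length filter bounds are inclusive", {
  sch <- scoring_scheme()
  for (case in list(c(1499, FALSE), c(1500, TRUE),
                    c(1600, TRUE), c(1601, FALSE))) {
    set.seed(case[1])
    s <- rand_seq(case[1])
    aln <- align_four_way(list(capuchin = s, marmoset = s), sch)
    expect_equal(filter_alignment_length(aln), as.logical(case[2]),
                 label = paste("columns", case[1]))
  }
  expect_error(align_four_way(list(capuchin = "ACGT")), "at least 2")
})
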