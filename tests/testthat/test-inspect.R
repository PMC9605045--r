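lib <- default_subfamily_library()
sch <- scoring_scheme()

## shared scaffold: a 1210 bp backbone with carriers planted at position 598
## (element 5' boundary at 610), TSD 12 bp, A-tail 25 bp
make_scaffold <- function(seed = 101) {
  set.seed(seed)
  bb <- rand_seq(1210)
  carrier <- plant_insertion(bb, 598, lib[["AluSc"]], 12, 25)
  list(bb = bb, carrier = carrier, alu_start = 610,
       alu_end = 610 + 290 + 25)
}

test_that("detect_tsd recovers a planted duplication exactly", {
  sc <- make_scaffold()
  tsd <- detect_tsd(sc$carrier, c(sc$alu_start, sc$alu_end))
  expect_s3_class(tsd, "tsd_call")
  expect_equal(tsd$left_end - tsd$left_start, 12)
  expect_equal(tsd$mismatches, 0)
  expect_identical(tsd$sequence,
                   substr(sc$carrier, sc$alu_start - 11, sc$alu_start))
  expect_identical(tsd$sequence,
                   substr(sc$carrier, sc$alu_end + 1, sc$alu_end + 12))
})

test_that("no duplication means no TSD call", {
  set.seed(102)
  bb <- rand_seq(400)
  expect_null(detect_tsd(bb, c(200, 230)))
})

test_that("a substituted right copy needs the mismatch allowance", {
  sc <- make_scaffold(103)
  seq <- sc$carrier
  hit0 <- detect_tsd(seq, c(sc$alu_start, sc$alu_end))
  ## substitute one base in the middle of the right copy
  p <- sc$alu_end + 6
  old <- substr(seq, p, p)
  substr(seq, p, p) <- if (old == "A") "G" else "A"
  strict <- detect_tsd(seq, c(sc$alu_start, sc$alu_end), max_mismatch = 0)
  loose <- detect_tsd(seq, c(sc$alu_start, sc$alu_end), max_mismatch = 1)
  ## at zero tolerance only a shorter sub-word (if any) remains
  expect_true(is.null(strict) ||
                (strict$left_end - strict$left_start) < 12)
  expect_equal(loose$left_end - loose$left_start, 12)
  expect_equal(loose$mismatches, 1)
  expect_equal(hit0$mismatches, 0)
})

test_that("detect_tsd matches brute-force enumeration on random inputs", {
  set.seed(104)
  for (rep in 1:300) {
    bb_len <- sample(80:160, 1)
    bb <- rand_seq(bb_len)
    alu_len <- sample(20:50, 1)
    tsd_len <- sample(6:18, 1)
    tail_len <- sample(0:12, 1)
    pos <- sample((tsd_len + 5):(bb_len - tsd_len - 5), 1)
    seq <- plant_insertion(bb, pos, rand_seq(alu_len), tsd_len, tail_len)
    if (runif(1) < 0.4) {   # sometimes corrupt the right copy
      p <- pos + tsd_len + alu_len + tail_len + sample(tsd_len, 1)
      substr(seq, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    s <- pos + tsd_len
    e <- s + alu_len + tail_len
    got <- detect_tsd(seq, c(s, e))
    want <- brute_tsd(seq, s, e)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$left_end - got$left_start, want$L)
      expect_equal(got$right_start - e, want$d)
      expect_equal(got$mismatches, want$mm)
      expect_identical(got$sequence, want$sequence)
    }
  }
})

test_that("the A-tail terminus estimate stops at the tail", {
  set.seed(105)
  seq <- paste0(rand_seq(50), strrep("A", 30), "CAAATCAC", rand_seq(50))
  expect_equal(alusort:::estimate_a_tail_end(seq, 50), 80)
  ## a substitution inside the tail does not derail the estimate
  substr(seq, 65, 65) <- "G"
  expect_equal(alusort:::estimate_a_tail_end(seq, 50), 80)
  ## no tail at all
  set.seed(106)
  gc_only <- paste(sample(c("G", "C"), 100, replace = TRUE), collapse = "")
  expect_equal(alusort:::estimate_a_tail_end(gc_only, 40), 40)
})

test_that("subfamily assignment discriminates the mock library", {
  exact <- assign_subfamily(lib[["AluTa7"]], lib, sch)
  expect_equal(exact$subfamily, "AluTa7")
  expect_equal(exact$divergence_pct, 0)

  set.seed(107)
  mut <- alusort:::mutate_seq(lib[["AluSc"]], 0.02)
  sc <- assign_subfamily(mut, lib, sch)
  expect_equal(sc$subfamily, "AluSc")
  expect_lt(abs(sc$divergence_pct - 2), 1.5)

  ## equidistant query ties break alphabetically
  tiny <- c(bbb = "ACGTACGTACGTACGTACGT", aaa = "ACGTACGTACGTACGTACGT")
  tie <- assign_subfamily("ACGTACGTACGTACGTACGT", tiny, sch)
  expect_equal(tie$subfamily, "aaa")

  junk <- assign_subfamily(rand_seq(300), lib, sch)
  expect_equal(junk$subfamily, "unclassified")
})

test_that("precise parallel flag follows subfamily lineages", {
  expect_false(flag_precise_parallel(c("Ta10", "Ta10")))
  expect_true(flag_precise_parallel(c("Ta10", "Sc")))
  expect_true(is.na(flag_precise_parallel(c("Ta15", "unclassified"))))
  expect_true(is.na(flag_precise_parallel("Ta15")))
  ## same lineage, different derived subfamily: no flag
  expect_false(flag_precise_parallel(c("Sc", "Sc8")))
  ## cross-lineage old-S vs Ta
  expect_true(flag_precise_parallel(c("Sx", "Ta7")))
})

cms_alignment <- function(o_row = NULL, m_row = NULL, seed = 101) {
  sc <- make_scaffold(seed)
  rows <- list(capuchin = sc$carrier,
               marmoset = m_row %||% sc$carrier,
               owl_monkey = o_row %||% sc$bb,
               squirrel_monkey = sc$carrier)
  list(aln = align_four_way(rows, sch, center = "capuchin"), sc = sc)
}

test_that("a clean three-carrier locus is validated as shared", {
  x <- cms_alignment()
  pattern <- c(capuchin = TRUE, marmoset = TRUE,
               owl_monkey = FALSE, squirrel_monkey = TRUE)
  out <- classify_inspection(x$aln, pattern, lib[["AluSc"]], sch,
                             library = lib)
  expect_equal(out$verdict, "shared")
  expect_equal(out$other_reason, "none")
  expect_equal(max(out$positions) - min(out$positions), 0)
  expect_false(is.null(out$tsd$marmoset))
  expect_true(all(out$subfamily[!is.na(out$subfamily)] == "AluSc"))
  expect_false(isTRUE(out$precise_parallel))
})

test_that("an offset second insertion with its own TSD is near parallel", {
  sc <- make_scaffold(108)
  np_row <- plant_insertion(sc$bb, 598 - 31, lib[["AluTa10"]], 10, 20)
  x <- cms_alignment(m_row = np_row, seed = 108)
  pattern <- c(capuchin = TRUE, marmoset = TRUE,
               owl_monkey = FALSE, squirrel_monkey = TRUE)
  out <- classify_inspection(x$aln, pattern, lib[["AluSc"]], sch,
                             library = lib)
  expect_equal(out$verdict, "near_parallel")
})

test_that("retained fragments in a nominally absent row fail inspection", {
  sc <- make_scaffold(109)
  frag_alu <- paste0(substr(lib[["AluSc"]], 1, 60),
                     substr(lib[["AluSc"]], 261, 290))
  frag_row <- plant_insertion(sc$bb, 598, frag_alu, 12, 25)
  ## the fragmented row must not be called present by scoring
  expect_false(score_alu_presence(frag_row, lib[["AluSc"]], sch)$present)
  x <- cms_alignment(o_row = frag_row, seed = 109)
  pattern <- c(capuchin = TRUE, marmoset = TRUE,
               owl_monkey = FALSE, squirrel_monkey = TRUE)
  out <- classify_inspection(x$aln, pattern, lib[["AluSc"]], sch,
                             library = lib)
  expect_equal(out$verdict, "other")
  expect_equal(out$other_reason, "present_in_all")
})

test_that("N-runs and short rows fail with their own reasons", {
  x <- cms_alignment(seed = 110)
  pattern <- c(capuchin = TRUE, marmoset = TRUE,
               owl_monkey = FALSE, squirrel_monkey = TRUE)
  n_aln <- x$aln
  row <- n_aln$rows[["marmoset"]]
  substr(row, 100, 250) <- strrep("N", 151)
  n_aln$rows[["marmoset"]] <- row
  out <- classify_inspection(n_aln, pattern, lib[["AluSc"]], sch)
  expect_equal(out$verdict, "other")
  expect_equal(out$other_reason, "has_N")

  sc <- make_scaffold(111)
  short <- substr(sc$bb, 1, 700)
  x2 <- cms_alignment(o_row = short, seed = 111)
  out2 <- classify_inspection(x2$aln, pattern, lib[["AluSc"]], sch)
  expect_equal(out2$verdict, "other")
  expect_equal(out2$other_reason, "truncated")
})

test_that("a carrier without a TSD is never validated as shared", {
  sc <- make_scaffold(112)
  ## element inserted without target site duplication
  no_tsd <- paste0(substr(sc$bb, 1, 610), lib[["AluSc"]], strrep("A", 25),
                   substr(sc$bb, 611, 1210))
  x <- cms_alignment(m_row = no_tsd, seed = 112)
  pattern <- c(capuchin = TRUE, marmoset = TRUE,
               owl_monkey = FALSE, squirrel_monkey = TRUE)
  out <- classify_inspection(x$aln, pattern, lib[["AluSc"]], sch)
  expect_true(out$verdict != "shared")
  expect_equal(out$verdict, "other")
})
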