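test_that("plant_insertion performs exact string surgery with a TSD", {
  out <- plant_insertion("ACGTACGTAC", 5, "TTTT", 2, 0)
  expect_identical(out, "ACGTACGTTTTCGTAC")
  expect_equal(nchar(out), 10 + 4 + 0 + 2)
  ## the duplicated bases flank the element on both sides
  expect_identical(substr(out, 6, 7), "CG")
  expect_identical(substr(out, 12, 13), "CG")

  big <- plant_insertion(strrep("ACGT", 750), 1500, rand_seq(300), 12, 20)
  expect_equal(nchar(big), 3000 + 300 + 20 + 12)
})

test_that("plant_insertion rejects invalid positions", {
  expect_error(plant_insertion("ACGTACGTAC", 2, "TT", 2, 0), "underflow")
  expect_error(plant_insertion("ACGTACGTAC", 9, "TT", 3, 0), "too close")
  expect_error(plant_insertion("ACGTACGTAC", 0, "TT", 1, 0), "position")
})

test_that("degenerate weights give an all-CMOS cohort", {
  cfg <- simulation_config(seed = 3, n_loci = 12,
                           category_weights = c(CMOS = 1),
                           per_lineage_divergence = 0)
  co <- simulate_cohort(cfg)
  expect_true(all(co$truth$true_category == "CMOS"))
  expect_true(all(co$truth$present_C & co$truth$present_M &
                    co$truth$present_O & co$truth$present_S))
  ## every ingroup genome carries the element; the outgroup never does
  expect_true(all(nchar(co$genomes$outgroup) == cfg$backbone_length))
  expect_true(all(nchar(co$genomes$capuchin) > cfg$backbone_length))
})

test_that("identical seed and config reproduce byte-identical outputs", {
  cfg <- simulation_config(seed = 7, n_loci = 8, np_event_rate = 0.2,
                           n_run_rate = 0.1)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_cohort(cfg, d1)
  simulate_cohort(cfg, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  }
})

test_that("event draws can be replayed independently from the seed", {
  cfg <- simulation_config(seed = 3, n_loci = 200, np_event_rate = 0.1)
  truth <- simulate_truth(cfg)
  ## independent replay of the documented draw contract
  set.seed(3)
  u_cat <- runif(200)
  cuts <- cumsum(cfg$category_weights)
  cat_replay <- names(cfg$category_weights)[
    findInterval(u_cat, c(0, cuts), rightmost.closed = TRUE)]
  u_ev <- runif(200)
  ev_replay <- ifelse(u_ev < 0.1, "near_parallel", "clean_shared")
  ev_replay[cat_replay == "none"] <- "outgroup_shared"
  ev_replay[ev_replay == "near_parallel" &
              nchar(cat_replay) < 2] <- "clean_shared"
  expect_identical(truth$true_category, cat_replay)
  expect_identical(truth$event_type, ev_replay)
  ## and the cohort builder's truth matches the truth-only pass
  co <- simulate_cohort(cfg)
  expect_identical(co$truth$event_type, truth$event_type)
})

test_that("category frequencies converge to the configured weights", {
  cfg <- simulation_config(seed = 31, n_loci = 2000)
  truth <- simulate_truth(cfg)
  w <- cfg$category_weights
  w <- w[w > 0]
  obs <- table(factor(truth$true_category, levels = names(w)))
  p <- suppressWarnings(stats::chisq.test(obs, p = w)$p.value)
  expect_gt(p, 0.01)
})

test_that("carriers get an exact TSD even under divergence", {
  cfg <- simulation_config(seed = 13, n_loci = 15,
                           per_lineage_divergence = 0.02)
  co <- simulate_cohort(cfg)
  tru <- co$truth
  ig <- ingroup_genomes()   # letter -> genome id
  for (i in seq_len(nrow(tru))) {
    for (letter in names(ig)) {
      gs <- tru[[paste0("ins_start_", letter)]][i]
      if (is.na(gs) || gs != tru$planted_position[i]) next
      seq <- co$genomes[[ig[[letter]]]][[tru$locus_id[i]]]
      tsd <- tru$tsd_sequence[i]
      ## left copy ends exactly at the element 5' boundary, untouched by
      ## the per-lineage substitution process
      expect_identical(substr(seq, gs - nchar(tsd) + 1, gs), tsd)
    }
  }
})

test_that("configuration validation catches inconsistent settings", {
  expect_error(simulation_config(category_weights = c(CMOS = 0.5)),
               "sum to 1")
  expect_error(simulation_config(flank_unique_length = 500), ">= 600")
  expect_error(simulation_config(tsd_length_range = c(16, 8)), "min, max")
  expect_error(simulation_config(np_event_rate = 0.7, n_run_rate = 0.5),
               "at most 1")
  expect_error(simulation_config(category_weights = c(BAD = 1)),
               "unknown category")
})
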