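---
title: "Categorizing Alu insertion presence/absence across four genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Categorizing Alu insertion presence/absence across four genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Alu elements are ~300 bp primate SINE retrotransposons. A new copy inserts
essentially irreversibly, duplicating a short stretch of host sequence on
both sides (the target site duplication, TSD) and carrying a 3' poly-A
tail. Because the empty (pre-integration) allele is the ancestral state
and precise excision is vanishingly rare, a shared insertion at an
orthologous position is close to an ideal cladistic marker: the genomes
that carry it share a common ancestor in which the insertion occurred.

In a rapid radiation, however, an insertion that was still polymorphic at
the time of successive speciation events can sort into descendant
lineages in patterns that contradict the species tree (incomplete lineage
sorting, ILS). With four ingroup genomes — capuchin (C), marmoset (M),
owl monkey (O) and squirrel monkey (S) — each locus is summarized by which
genomes carry the element: 15 possible non-empty presence patterns, from
CMOS (all four) down to the four lineage-private classes. Tabulating
loci per category, after careful validation, measures how much ILS the
radiation produced and which three-of-four patterns dominate.

`alusort` implements the full desk side of that workflow:

1. **Ascertainment** (`parse_repeat_annotations`, `select_full_length`,
   `extract_locus_with_flanks`): full-length Alu annotations (span >= 267
   bp, alignment starting <= 4 bp into the consensus, both bounds
   inclusive) are cut out with 600 bp of flanking sequence on each side.
2. **Lineage specificity** (`check_lineage_specific`): BLAT-style PSL
   hits of the flank+element+flank query against an outgroup genome must
   show both flanks anchored colinearly with an insertion-sized
   (250-500 bp by default) query-only gap between them; otherwise the
   element predates the ingroup/outgroup split and is discarded.
3. **Orthologs and alignment** (`fetch_orthologs`, `align_four_way`):
   orthologous regions from the other three genomes are fetched via their
   PSL anchors and aligned star-progressively around the ascertainment
   sequence. Only alignments of 1500-1600 columns (inclusive) are
   analyzed: the ideal span is 600 + ~300 + 600, and anything much longer
   indicates extra intervening sequence.
4. **Presence scoring and category** (`score_alu_presence`,
   `assign_category`): each row is scored against an AluS-style consensus
   under the asymmetric gap scheme (below); rows reaching half the
   maximum attainable score are called present, and the category label
   concatenates the carrier letters in fixed C, M, O, S order.
5. **Deduplication** (`dedupe_candidates`): the same insertion is found
   once per carrier genome; records within 50 bp on the common reference
   collapse to the lowest-numbered ascertainment set.
6. **Inspection** (`classify_inspection`): automated surrogate for visual
   alignment review — validates shared calls by position agreement, TSDs
   and sequence congruence, and sorts failures into near-parallel
   insertions versus N-runs, truncations and elements actually present
   in all genomes.
7. **Reporting** (`summarize`, `pool_pcr`): per-category candidate /
   duplicate / unique / post-inspection tables with percentages rendered
   half-up at display precision, and pooled PCR confirmation arithmetic.

## The scoring scheme

All pairwise alignment — ortholog alignment, presence scoring, subfamily
assignment — uses one global affine scheme (`scoring_scheme()`): match
1.3, mismatch 0, and gap open/extend scores that depend on which sequence
the gap falls in and where:

| gap class            | open | extend |
|----------------------|------|--------|
| target left overhang | -2   | 0      |
| target right overhang| -1   | 0      |
| target internal      | -5   | -3     |
| query left overhang  | -1   | -1     |
| query right overhang | -2   | 0      |
| query internal       | -5   | -3     |

The asymmetry is the point. For presence scoring the consensus is placed
on the *target* side, so dropping a 290 bp consensus onto a ~1500 bp row
costs at most 3 points of end gaps: an intact element scores near the
maximum `1.3 * length(consensus)`, while a deleted or fragmented element
pays -5/-3 internal gaps and falls far below the 50% presence threshold.
Mismatches costing 0 makes the scheme tolerant of substitution decay
(~20 My of drift) without rewarding it. The implementation is an exact
three-state dynamic program (Rcpp); an optional diagonal band accelerates
the near-colinear ortholog alignments and falls back to the full matrix
whenever the band would clip the optimum. `align_four_way` merges the
pairwise alignments star-wise around the ascertainment sequence under the
usual "once a gap, always a gap" rule, and never mutates row content.

A note on sidedness: the gap vocabulary follows the convention of the
generic pairwise aligners used for this kind of consensus scoring — a
"target gap" is a dash in the target row. Scoring a long row against a
short consensus only behaves as described (cheap row overhang, expensive
internal surgery) with the consensus as target; `score_alu_presence`
therefore fixes that orientation internally.

## Inspection: from eyeballs to rules

Visual inspection is operationalized with a small number of explicit
knobs, all exposed as arguments:

* **TSD detection** (`detect_tsd`): longest duplicated word (6-25 bp)
  with at most 1 substitution, left copy ending exactly at the element's
  5' boundary, right copy beginning within 5 bp after the A-tail;
  preference longest, then fewest mismatches, then leftmost. This is
  checked in tests against brute-force enumeration of every
  (length, offset) pair.
* **A-tail terminus**: the scored-run estimate — first maximizer of
  `#A - 3 * #non-A` walking 3' from the consensus match end. The penalty
  makes the score peak at the true terminus even with scattered
  substitutions inside the tail, and ordinary downstream sequence
  (including an A-rich TSD copy) cannot extend it. A simpler
  fixed-tolerance rule ("at most 1 non-A per 10") proved fragile at 2%
  divergence — two nearby substitutions truncate the estimate and strand
  the TSD search — which is why the scored-run form is the default.
* **Shared validation**: all carriers' insertion start columns within 10
  (`np_offset_threshold`), every carrier anchored by a TSD, and all TSD
  pairs compatible (<= 1 mismatch over their common boundary-anchored
  suffix).
* **Near parallel**: carrier start columns differing by more than 10, or
  incompatible TSDs — independent insertions at nearby positions always
  create their own, different duplications.
* **Other**: any row with >= 5% N content (`has_N`); any expected row
  missing or shorter than 80% of its expected flank(+element) length
  (`truncated`); or a nominally absent row still containing >= 10% of
  some library consensus' exact 20-mers (`present_in_all` — the
  fragmented-element case where global scoring correctly refuses a
  presence call but pieces of the element are plainly there). A carrier
  without any detectable TSD cannot be validated and falls back to
  `truncated` ("undetermined status") rather than being guessed shared.

Precedence is has_N, truncated, present_in_all, then the
near-parallel/shared decision; corruption classes are judged before
position/TSD logic because they invalidate the evidence that logic needs.

* **Subfamily and precise parallels** (`assign_subfamily`,
  `flag_precise_parallel`): each carrier's element is assigned the
  best-scoring library consensus (ties alphabetical; below the presence
  threshold is "unclassified"). Shared calls whose carriers belong to
  different subfamily *lineages* (Sc-derived vs Ta10-derived vs
  Ta15-derived vs older S) are flagged as possible precise parallel
  insertions — two independent integrations at the same position.
  Same-lineage disagreement is attributed to decay and not flagged;
  unclassified carriers give an indeterminate (NA) flag.

## The synthetic cohort generator

`simulate_cohort()` produces the five-genome study system: one contig
per locus in four ingroup genomes plus an outgroup, each locus a shared
3000 bp unique backbone, with the element planted per the drawn category
and decayed per lineage. It emits exactly the file types the pipeline
consumes (FASTA, RepeatMasker `.out`, PSL anchor hits) plus a truth
table, so every stage is exercised through its real parsers.

Default study conditions, chosen once:

* Mock subfamily library: four synthetic 290 bp consensuses (AluSc,
  AluTa7, AluTa10, AluTa15) sharing a backbone and differing at 8-9
  diagnostic sites. They are labelled synthetic stand-ins — no repeat
  library content is redistributed — and real consensuses can be dropped
  in. 290 bp + a 10-40 bp tail gives insertions of 300-330 bp
  (matching the ~300 bp average element including tail) and total
  extracted spans of 1500-1530 bp, inside the 1500-1600 analysis window.
* TSD length 8-16 bp, A-tail 10-40 bp, insertion point mid-backbone
  (jittered ±100 bp), per-lineage divergence 0.02 — independent
  site-wise substitutions applied after planting, so flanks and element
  decay together. The two TSD copies are exempt from decay: carriers are
  guaranteed an exact duplication, which keeps the generator's contract
  ("flanked by an exact duplicated target site") and makes TSD-based
  validation a test of the detector, not of mutational luck.
* Category weights: 70% spread over the ten multi-genome categories in
  proportion to the observed unique-call frequencies of the comparative
  study, 15% CMOS, 3.25% per lineage-private class, 2% outgroup-private.
* Corruption events (all default 0; rates are drawn per locus in a
  documented two-pass RNG contract that tests replay independently):
  near-parallel pairs (second carrier gets a different-subfamily element
  offset 10-60 bp with its own TSD), N-runs (150 bp in one genome's
  flank), truncations (one non-essential genome's contig cut just past
  the element, so the locus always remains ascertainable from another
  carrier and flows to inspection), and fragmented present-in-all rows
  (internal deletion of consensus bases 60-260, leaving ~31% of the
  element: below the presence threshold but rich in diagnostic k-mers).

What the generator deliberately does not emulate: genome-scale repeat
density (one locus per contig, no nested or flanking repeats), indel
mutation (substitutions only, so orthologs stay colinear), assembly
artifacts beyond N-runs and truncations, minus-strand planting
(extraction's strand handling is unit-tested separately), and realistic
Alu sequence content. Passing recovery tests therefore demonstrates the
pipeline's logic under controlled decay and corruption, not performance
on real assemblies, where flank repeats, segmental duplications and
alignment ambiguity add failure modes the simulator does not model.

## Numerical conventions

* Coordinates are 0-based half-open everywhere internally; the
  RepeatMasker and PSL writers/parsers convert to and from their native
  conventions (1-based inclusive `.out`; `(left) end begin` consensus
  columns on the minus strand, normalized to a 5' offset = begin - 1).
* Best-hit and tie-break rules are deterministic and documented: maximal
  summed block length, then lexicographic target contig, then lowest
  target coordinate; subfamily ties alphabetical; dedup representative =
  lowest set number.
* Percentages are rounded half away from zero at display precision
  (integer for per-category retention and PCR rates, one decimal for the
  pooled shared/NP/other fractions); the summary tables reproduce every
  published figure exactly under this rule.
* Degenerate inputs have defined behaviour: empty rows score `-Inf` and
  are never present; the all-absent pattern is an error, not a 16th
  category; zero-denominator percentages render as an em dash.

## Problem sizes used in the tests

Unit tests run on toy sequences and cohorts of 8-40 loci. The
study-scale checks simulate 500 loci per condition: a clean cohort
(zero divergence, no corruption) must be recovered perfectly — every
ascertained locus passes the length filter, every pattern, category and
shared verdict matches truth — and a corrupted cohort (2% divergence,
10% near-parallel, 5% N-run, 5% truncation) must give a verdict vs
event-type confusion matrix at least 95% diagonal with no clean locus
miscalled near-parallel. `scripts/acceptance.R` re-runs both conditions
from scratch at a caller-chosen seed.

## Known limitations

* The star-progressive aligner is exact per pair but greedy across rows;
  with more divergent sequences a simultaneous multiple aligner (MUSCLE
  in real mode) can find better column assignments. The star path is the
  dependency-free default and the one the tests certify.
* Fragment detection by exact k-mer share assumes modest divergence
  (at 2% about two-thirds of 20-mers survive); deeply decayed fragments
  in real data would need a local-alignment probe instead.
* Dedup relies on caller-supplied coordinates on a common reference; the
  simulator's colinear loci make that projection trivial, real data
  requires anchoring first.
* The pipeline reports category evidence only; it deliberately stops
  short of tree inference.
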