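Package: alusort
Title: Alu Insertion Presence/Absence Categorization Across Primate Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative ascertainment of full-length Alu SINE
    insertions across four ingroup genomes and one outgroup. Parses
    RepeatMasker annotations, extracts full-length Alu loci with 600 bp
    flanks, tests lineage specificity against the outgroup via PSL (BLAT)
    anchor hits, builds four-way orthologous alignments under an
    asymmetric affine gap scoring scheme, scores each genome for presence
    or absence of the element against an AluS-style consensus, assigns
    each locus to one of the fifteen presence/absence categories, and
    automates post-alignment inspection (target site duplications,
    near-parallel insertions, N-runs, truncations, subfamily agreement).
    Includes a synthetic five-genome cohort simulator with planted
    insertions and a ground-truth table, so that every stage of the
    pipeline can be exercised and benchmarked at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
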