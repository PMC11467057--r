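Package: famsim
Title: Protein Family Similarity from Per-Residue Embeddings
Version: 0.1.0
Authors@R:
    person("famsim", "developers", email = "famsim@example.org",
           role = c("aut", "cre"))
Description: Turns per-residue neural-network embeddings and per-residue
    family-probability matrices into domain calls, family embeddings and
    normalized pairwise family-similarity scores; evaluates those scores
    against clan labels or structure-based (TM-score) ground truth using
    sensitivity curves and TP-at-fixed-FP statistics; and clusters families
    into candidate clans with Leiden community detection. Includes a full
    synthetic-corpus generator with planted clan structure, sticky
    (coiled-coil-like) families and nested/adjacent/shared-neighbour
    failure-mode scenarios, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
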