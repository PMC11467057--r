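---
title: "famsim: methods, synthetic worlds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{famsim: methods, synthetic worlds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`famsim` scores pairwise similarity between protein domain families using
only two per-residue artifacts of a family classifier: an embedding matrix
(L x D per sequence) and a class-probability matrix (L x C). The pipeline
is deliberately simple and has few tunable parameters.

**Domain calling.** For each family class independently, every maximal run
of consecutive residues whose class probability is strictly above
`prob_threshold` becomes a call if the run is at least `min_length`
residues. Two readings of the published rule were possible — per-class runs
or runs of the max across classes — and the per-class reading is
implemented: it matches the per-family rows of the probability-matrix
illustration, and it is exactly the mechanism that lets nested domains
produce overlapping calls. "Above" is read strictly (`p > 0.025`): a
residue at exactly the threshold breaks a run. `min_length` is inclusive
("at least 20").

**Aggregation.** A domain embedding is the arithmetic mean of the
per-residue embeddings across the called span; a family embedding is the
unweighted mean of its domain embeddings — each instance counts once,
regardless of span length, because averaging is defined per instance, not
per residue. Families with no calls are absent from all downstream
matrices; `coverage_report()` accounts for them against the clan-map
universe. The per-call `mean_probability` (arithmetic mean of the class
probability over the span) is carried for reporting only; no per-call score
is defined by the method.

**Scoring.** Raw similarity is cosine between family embeddings. Each row
of the raw matrix is then z-normalized with its own empirical moments:
`mu_i` and `sigma_i` are the mean and *population* standard deviation
(ddof = 0) of the F-1 off-diagonal entries of row i. The self-similarity
(identically 1) is excluded from the moments — whether the original
procedure included it is unstated, but including a constant spike would
bias the Gaussian approximation; the choice is flagged for sensitivity
checking and makes no practical difference at realistic F. The "Gaussian
approximation" is plain moment standardization; no distribution is fitted.
A constant row (sigma = 0) is normalized to zeros with a warning naming
the family rather than erroring, since one degenerate family should not
abort a corpus-scale run. The diagonal is carried as `NA` end-to-end so no
evaluation can consume self-pairs. The final pair score is the maximum of
the two directed normalized scores; `mean` and `min` are provided for the
ablation, and `max >= mean >= min` holds entrywise by construction.

**Evaluation.** Non-ignored pairs are ranked by score, descending; ties are
broken by family accession for determinism, and tie blocks are recorded so
a cutoff straddling a tie can be detected. TP@kFP is the maximum cumulative
TP over prefixes with at most k false positives — this is the robust
reading of "exactly k errors" when the k-th and (k+1)-th FP tie. The
published work does not state its tie handling; the deterministic
convention here is a package choice, not a fact about the method.
`threshold_at_fdr()` scans prefixes ending at distinct scores and returns
the lowest prefix-end score whose FDR (100·FP/(FP+TP)) meets the target.
Clan labeling: positive iff both families share a clan; *conservative*
negatives require both families to have (different) clans, anything
touching a clanless family is ignored; *liberal* negatives are everything
not positive. Structure labeling: positive at TM >= `pos_th` (0.5,
"equal or higher"), negative strictly below `neg_th` (0.17, the expected
score of random structure pairs), ignored in between, when the pair is
missing, or when either family lacks a structural model.

**Clustering.** Edges are kept where the final score strictly exceeds the
threshold (the published operating point, 6.48, is the score at 1%
conservative FDR at corpus scale; on synthetic corpora the analogous
threshold is recomputed from the curve). Leiden is delegated to igraph with
the modularity objective, resolution 1.0 and edge weights on by default —
none of these are stated by the source method, so they are package-level
choices; a seed is mandatory and the assignment is reproducible given the
seed and igraph version. The cluster report flags clanless members of
majority-one-clan clusters (> 0.5 of labeled members, a reporting
heuristic) as new-member candidates, multi-clan clusters as merge
candidates and all-clanless clusters as new-clan candidates.

## The synthetic stated world

`generate_corpus()` emulates the statistical structure the method assumes,
not biology: no amino-acid sequences or structures are simulated.

* Family directions: family f in clan k points along
  `u_f = alpha*c_k + beta*v_f` with `c_k`, `v_f` random unit vectors
  (defaults alpha = 1.2, beta = 0.5, giving clan-mate cosine ~0.85 and
  cross-clan cosine ~0). Clanless families get a private core direction.
* Residue embeddings: the span signal is smoothed along the length axis
  with an exponential kernel (`rho^|d|`, unit mass, rho = 0.9) and
  stationary AR(1) noise (sd 0.3, same rho) is added. AR(1) is the
  simplest process giving the observed smoothness — adjacent residues more
  similar than distant ones — and the kernel is also the mechanism for
  context leakage between adjacent domains.
* Probabilities: ~0.9 (U(0.85, 0.95)) on the true family inside spans,
  < 0.005 outside, so default calling recovers the true spans.
* TM scores: clan-mates ~ N(0.65, 0.08), everything else ~ N(0.10, 0.04),
  clipped to [0, 1] — the structure benchmark agrees with the clan labels
  by construction. That is an assumption of the fixture, not of the method.
* Defaults: 4 clans x 10 families, 10 sequences per family, domain length
  30–80, D = 32 (kept small for test speed; at D = 32 random-direction
  overlaps contribute cosine noise ~ 1/sqrt(D) ≈ 0.18, which matters below).

**Sticky families.** The coiled-coil analog is a *group*: sticky families
are clanless and share a dedicated blob direction with weight
`sticky_offset` (1.5, blob-internal cosine ~0.9). This is a deliberate
design point. A single sticky family cannot be what the normalization
fixes: the raw matrix is symmetric, so an elevated row is also an elevated
column, row z-normalization removes only the row effect, and the max
aggregation then picks the surviving column effect up from every other
family's row. For a blob occupying fraction p of each row, however, the
blob entries' z-score within any row is bounded by sqrt((1-p)/p) — a mass
of entries cannot all be outliers — which is exactly why normalization
neutralizes a sizeable sticky group while raw cosine ranking is flooded by
its quadratically many internal pairs. At desk scale this requires a
substantial blob (the packaged experiment uses 20 sticky families against
40 clan families, at D = 128 so that direction-overlap noise does not blur
the clan margin). The experiment is evaluated with *liberal* labels:
sticky families are clanless, and under the conservative definition their
pairs would be ignored and stickiness could not create false positives at
all.

**Failure modes.** Planted scenarios add co-occurrence sequences for
existing (clanless) families: nested — B's span strictly inside A's on
every co-sequence, so the shared residues (whose signal is the sum of both
directions) enter both families' averages; adjacent — B starts within
`plant_gap` (<= 2) residues of A's end, and the smoothing kernel leaks each
family's signal into the other's span; shared neighbour — X–Z and Y–Z
adjacent while X and Y never co-occur. Planted spans use
`plant_span_length` = 20 (the shortest callable span) and
`plant_sequences` = 3x the solo count: context leakage is proportionally
strongest when spans are short relative to the kernel and when
co-occurrence dominates a family's instances — which is the regime the
real failure cases occupy (the problematic pairs co-occur in most of their
instances). The packaged experiment uses D = 128 for the same
noise-margin reason as above.

**What a green test establishes.** The generator produces linearly
separable clan structure with homogeneous noise and a structure benchmark
tied to the clans; real embeddings have heterogeneous family sizes, varying
SNR, and clans of wildly different tightness. Green recovery tests
establish that the pipeline's machinery (calling, averaging, normalization,
ranking, clustering) is correct and that the documented mechanisms (sticky
inflation, nested/adjacent contamination) behave as described — not that
the method achieves any particular accuracy on real proteins. The
control assertion in the failure-mode test uses the *median* of the
unplanted control pairs (below the unrelated 95th percentile): any single
unplanted pair exceeds a 95th percentile with 5% probability by
definition, so a per-pair control would be a coin flip.

## Numerical choices and degenerate inputs

* Spans are 0-based half-open in memory, 1-based inclusive on disk
  (flat-file convention); conversions are round-trip tested.
* TSV floats are written with 6 significant digits; the binary container
  stores float32 (full single precision). The container is a single file —
  magic, JSON index, float32 payload — supporting partial reads by key; it
  mirrors an HDF5 group of 2-D datasets without requiring an HDF5 binding.
* Normalization needs F >= 3 families (two off-diagonal values per row);
  fewer is an error, not a silent NaN.
* `midpoint_overlap` implements the stated asymmetric either-direction
  rule (> 50% of prediction OR > 50% of reference) and is tested against
  direct interval arithmetic.
* Errors are classed conditions (`famsim_error_*`) so callers can
  distinguish missing files, dimension mismatches, NaN payloads, range
  violations and degenerate label sets programmatically.
* All randomness flows through explicit seeds: `corpus_config(seed = )`
  for generation (identical seeds are bit-identical), a derived
  deterministic seed for each planting operation unless one is supplied,
  and a mandatory seed for Leiden.

## Known limitations

* The dense F x F matrix is computed as such; at F ~ 17k (~300M pairs)
  this is supported but memory-heavy and not optimized (no approximate
  nearest-neighbour search, by design).
* The co-occurrence statistics are diagnostic only; no correction is
  applied to the scores (corrections were explored by the source method
  and rejected as degrading performance).
* Ensemble averaging across classifier replicas is out of scope: each
  embedding/probability source is treated independently, and
  `select_best_source()` picks among sources by TP@kFP.
* The sticky mechanism models group stickiness; an isolated sticky family
  is provably not fixable by row normalization under max aggregation (see
  above), and the package makes no claim to handle that case.
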