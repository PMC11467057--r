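# famsim

Protein family similarity from per-residue neural-network embeddings.

## The problem

Protein domain families (in the style of Pfam) are grouped into *clans* when
they are believed to share an evolutionary origin, but most families carry no
clan label and many are domains of unknown function. Per-residue family
classifiers emit, for every residue of a protein, an embedding vector and a
vector of family-class probabilities. `famsim` turns those two per-residue
artifacts into a calibrated family-vs-family similarity score and the
downstream analyses that make the score useful for clan curation:

1. **Domain calling** — a domain call is a maximal run of residues whose
   probability for one family class stays strictly above a threshold
   (default 0.025), kept if the run is at least `min_length` residues
   (default 20). Calling is per class, so nested domains produce
   overlapping calls.
2. **Embedding aggregation** — the *domain embedding* is the mean of the
   per-residue embeddings over a called span; the *family embedding* is the
   unweighted mean of all domain embeddings labeled with that family.
3. **Scoring** — with family embeddings u_i, raw similarity is cosine,
   `sim(i,j) = <u_i,u_j> / (|u_i||u_j|)`. Each family's distribution of raw
   similarities to all other families is standardized with its own moments
   (mu_i, sigma_i over the off-diagonal row):

       normed_sim(i,j) = (sim(i,j) - mu_i) / sigma_i
       score(i,j)      = max(normed_sim(i,j), normed_sim(j,i))

   The per-family z-normalization puts "sticky" families (coiled coils,
   disordered regions — uniformly similar to everything) on the same scale
   as everyone else; the max-symmetrization means a pair is confident if at
   least one direction is.
4. **Evaluation** — pairs are labeled positive/negative/ignored from a clan
   map (conservative: a false positive requires two *different* clans;
   liberal: anything not same-clan is negative) or from a TM-score table
   (positive at TM >= 0.5, negative below 0.17). The headline statistic is
   TP@kFP: true positives accumulated before more than k false positives,
   read off a sensitivity curve, alongside FDR thresholds and ROC AUC.
5. **Clustering** — families become nodes of a graph with edges wherever
   the score exceeds a threshold (typically the score at 1% conservative
   FDR); Leiden communities are compared against the existing clan
   annotation to flag new-member candidates, clan merges and new clans.
6. **Synthetic corpora** — a generator plants clan structure, smooth
   (AR(1)) residue embeddings, sticky family blobs and the classic failure
   modes (nested, adjacent, shared-neighbour domains), so the whole
   pipeline is testable offline with known ground truth.

## Worked example

```r
library(famsim)
corpus <- generate_corpus(corpus_config(n_clans = 3, families_per_clan = 4,
                                        sequences_per_family = 8, seed = 7))
res <- score_corpus(corpus)        # call -> embed -> cosine -> z -> max
res$final
#> <final_scores: 12 families, method = max>

labels <- label_pairs_by_clan(res$final$family, corpus$clan_map, "conservative")
curve <- sensitivity_curve(res$final, labels)
curve
#> <sensitivity_curve: 66 pairs, 18 TP, 48 FP total>
tp_at_fp(curve, 10)                # 18 of 18 clan pairs recovered
#> [1] 18
round(threshold_at_fdr(curve, 1), 3)
#> [1] 1.18

asg <- leiden_clusters(build_graph(res$final, threshold_at_fdr(curve, 1)),
                       seed = 7)
adjusted_rand_index(asg, clan_of(corpus$clan_map, names(asg)))
#> [1] 1
```

All 12 planted families are scored; every same-clan pair outranks every
cross-clan pair (TP@10FP = 18/18), and Leiden clustering of the graph
thresholded at the 1%-FDR score reproduces the three planted clans exactly
(adjusted Rand index 1).

## Command line

`inst/cli/famsim` wires the subcommands with the published defaults
(min length 20, probability 0.025, clustering threshold 6.48, TM 0.5/0.17,
k = 100):

```sh
famsim simulate --out-dir corpus/ --seed 1
famsim call     --probs corpus/probabilities.bin --out calls.tsv
famsim embed    --embeddings corpus/embeddings.bin --calls calls.tsv --out famemb.bin
famsim score    --famemb famemb.bin --out scores.tsv
famsim evaluate --scores scores.tsv --clans corpus/clans.tsv --out curve.tsv
famsim cluster  --scores scores.tsv --clans corpus/clans.tsv --seed 1 \
                --out clusters.tsv --report report.tsv
```

Global flags `--seed`, `--log-level`, `--config` (JSON, one object per
subcommand; flags override file values).

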