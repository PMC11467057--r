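small_cfg <- function(...) {
  corpus_config(n_clans = 2L, families_per_clan = 3L,
                sequences_per_family = 5L, embedding_dim = 16L,
                seed = 77L, ...)
}

test_that("generate_corpus bookkeeping matches the config", {
  cfg <- corpus_config(n_clans = 2, families_per_clan = 3,
                       sequences_per_family = 10, embedding_dim = 16,
                       seed = 5)
  corpus <- generate_corpus(cfg)
  expect_length(corpus$embeddings, 60)
  expect_length(corpus$probabilities, 60)
  expect_equal(nrow(corpus$clan_map), 6)
  expect_equal(sort(unique(corpus$clan_map$clan)), c("CL0001", "CL0002"))
  expect_equal(nrow(corpus$tm), choose(6, 2))
  expect_equal(attr(corpus$embeddings, "embedding_dim"), 16L)
  # true spans lie inside their sequences and probabilities are valid
  sp <- corpus$truth$spans
  lens <- vapply(corpus$embeddings, nrow, integer(1))
  expect_true(all(sp$end <= lens[sp$sequence_id]))
  expect_true(all(sp$start >= 0))
})

test_that("identical seeds give bit-identical corpora, different seeds differ", {
  c1 <- generate_corpus(small_cfg())
  c2 <- generate_corpus(small_cfg())
  expect_identical(c1$embeddings, c2$embeddings)
  expect_identical(c1$probabilities, c2$probabilities)
  expect_identical(c1$tm, c2$tm)
  c3 <- generate_corpus(corpus_config(n_clans = 2, families_per_clan = 3,
                                      sequences_per_family = 5,
                                      embedding_dim = 16, seed = 78))
  expect_false(identical(c1$embeddings, c3$embeddings))
})

test_that("config validation catches bad worlds", {
  expect_error(corpus_config(rho = 1), class = "famsim_error_invalid_config")
  expect_error(corpus_config(n_clans = -1), class = "famsim_error_invalid_config")
  expect_error(corpus_config(embedding_dim = 1),
               class = "famsim_error_invalid_config")
  expect_error(corpus_config(nested_pairs = 1),   # needs clanless families
               class = "famsim_error_invalid_config")
})

test_that("TM scores separate clan-mates from the rest by construction", {
  corpus <- generate_corpus(small_cfg())
  cl <- clan_of(corpus$clan_map, corpus$tm$family_i)
  cl2 <- clan_of(corpus$clan_map, corpus$tm$family_j)
  mates <- !is.na(cl) & !is.na(cl2) & cl == cl2
  expect_gt(min(corpus$tm$tm_score[mates]), max(corpus$tm$tm_score[!mates]))
  expect_true(all(corpus$tm$tm_score >= 0 & corpus$tm$tm_score <= 1))
})

test_that("sticky families have inflated mean raw cosine", {
  corpus <- generate_corpus(corpus_config(
    n_clans = 2, families_per_clan = 4, sticky_family_count = 4,
    sequences_per_family = 5, embedding_dim = 32, seed = 31))
  res <- score_corpus(corpus)
  m <- res$raw$matrix; diag(m) <- NA
  sticky <- corpus$truth$families$family[corpus$truth$families$sticky]
  others <- setdiff(res$raw$family, sticky)
  expect_gt(mean(rowMeans(m[sticky, ], na.rm = TRUE)),
            mean(rowMeans(m[others, ], na.rm = TRUE)))
})

test_that("alpha = 0 removes the clan signal from the final scores", {
  corpus <- generate_corpus(corpus_config(
    n_clans = 2, families_per_clan = 6, sequences_per_family = 5,
    embedding_dim = 16, alpha = 0, seed = 13))
  res <- score_corpus(corpus)
  ps <- pair_scores(res$final)
  cl <- clan_of(corpus$clan_map, ps$fam_i)
  cl2 <- clan_of(corpus$clan_map, ps$fam_j)
  mates <- cl == cl2
  ks <- suppressWarnings(stats::ks.test(ps$score[mates], ps$score[!mates]))
  expect_gt(ks$p.value, 0.01)
})

test_that("planting reshapes co-occurrence exactly as specified", {
  corpus <- generate_corpus(corpus_config(
    n_clans = 1, families_per_clan = 2, n_clanless_families = 5,
    sequences_per_family = 4, embedding_dim = 16, plant_sequences = 6,
    seed = 3))
  fams <- corpus$truth$families$family
  clanless <- fams[is.na(corpus$truth$families$clan)]
  corpus <- plant_nested_pair(corpus, clanless[1], clanless[2])
  corpus <- plant_shared_neighbor(corpus, clanless[3], clanless[4], clanless[5])
  expect_equal(corpus$truth$planted$kind, c("nested", "shared_neighbor"))

  calls <- call_domains_store(corpus$probabilities)
  st <- cooccurrence_stats(calls, gap = corpus$truth$config$plant_gap)
  row_of <- function(a, b) {
    st[st$family_i == min(a, b) & st$family_j == max(a, b), ]
  }
  nest <- row_of(clanless[1], clanless[2])
  expect_equal(nest$n_same_sequence, 6L)
  expect_equal(nest$n_residue_overlap, 6L)
  # X and Y each adjacent to Z, never with each other
  expect_equal(row_of(clanless[3], clanless[5])$n_adjacent, 6L)
  expect_equal(row_of(clanless[4], clanless[5])$n_adjacent, 6L)
  expect_equal(nrow(row_of(clanless[3], clanless[4])), 0L)
  # nested spans really are strictly inside on every co-sequence
  sp <- corpus$truth$spans
  nested_seqs <- grep("^nest_", sp$sequence_id, value = TRUE)
  for (sid in unique(nested_seqs)) {
    s <- sp[sp$sequence_id == sid, ]
    outer <- s[s$family == clanless[1], ]
    inner <- s[s$family == clanless[2], ]
    expect_true(inner$start > outer$start && inner$end < outer$end)
  }
  expect_error(plant_nested_pair(corpus, "PF99999", clanless[1]),
               class = "famsim_error_unknown_family")
})

test_that("probability matrices put mass on the true family inside spans", {
  corpus <- generate_corpus(small_cfg())
  sp <- corpus$truth$spans[1, ]
  p <- corpus$probabilities[[sp$sequence_id]]
  cls <- attr(corpus$probabilities, "classes")
  inside <- p[(sp$start + 1):sp$end, match(sp$family, cls)]
  expect_true(all(inside > 0.8))
  outside <- p[-((sp$start + 1):sp$end), match(sp$family, cls)]
  expect_true(all(outside < 0.025))
})
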