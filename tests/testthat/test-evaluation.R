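cm4 <- clan_map(c("w", "x", "y", "z"), c("CL0001", "CL0001", "CL0002", NA))

test_that("clan labeling follows the conservative and liberal definitions", {
  cons <- label_pairs_by_clan(c("w", "x", "y", "z"), cm4, "conservative")
  lib <- label_pairs_by_clan(c("w", "x", "y", "z"), cm4, "liberal")
  get <- function(df, a, b) df$label[df$fam_i == a & df$fam_j == b]
  expect_equal(get(cons, "w", "x"), "positive")
  expect_equal(get(lib, "w", "x"), "positive")
  expect_equal(get(cons, "w", "y"), "negative")
  expect_equal(get(lib, "w", "y"), "negative")
  expect_equal(get(cons, "w", "z"), "ignored")   # clanless partner
  expect_equal(get(lib, "w", "z"), "negative")
  expect_error(label_pairs_by_clan(c("w", "nope"), cm4),
               class = "famsim_error_unknown_family")
})

test_that("conservative non-ignored pairs are a subset of liberal ones", {
  set.seed(12)
  fams <- sprintf("F%02d", 1:20)
  cm <- clan_map(fams, sample(c("CL1", "CL2", "CL3", NA), 20, replace = TRUE))
  cons <- label_pairs_by_clan(fams, cm, "conservative")
  lib <- label_pairs_by_clan(fams, cm, "liberal")
  expect_true(all(lib$label[cons$label != "ignored"] != "ignored"))
  expect_true(all(lib$label != "ignored"))
  expect_lte(sum(cons$label == "negative"), sum(lib$label == "negative"))
  expect_equal(cons$label == "positive", lib$label == "positive")
})

test_that("structure labeling applies pos/neg thresholds with stated equality", {
  tm <- tm_score_table(rep("a", 5), c("b", "c", "d", "e", "f"),
                       c(0.6, 0.10, 0.30, 0.5, 0.17))
  labs <- label_pairs_by_structure(letters[1:6], tm)
  get <- function(b) labs$label[labs$fam_i == "a" & labs$fam_j == b]
  expect_equal(get("b"), "positive")     # 0.60
  expect_equal(get("c"), "negative")     # 0.10
  expect_equal(get("d"), "ignored")      # 0.30, twilight zone
  expect_equal(get("e"), "positive")     # exactly pos_th: equal or higher
  expect_equal(get("f"), "ignored")      # exactly neg_th: "lower" is strict
  # pairs absent from the table are ignored
  expect_equal(labs$label[labs$fam_i == "b" & labs$fam_j == "c"], "ignored")
  # families without a model are ignored even with a TM score
  labs2 <- label_pairs_by_structure(letters[1:6], tm,
                                    families_with_models = c("a", "c"))
  expect_equal(labs2$label[labs2$fam_i == "a" & labs2$fam_j == "b"], "ignored")
  expect_equal(labs2$label[labs2$fam_i == "a" & labs2$fam_j == "c"], "negative")
})

test_that("structure labels partition non-ignored pairs exhaustively", {
  set.seed(14)
  fams <- sprintf("F%02d", 1:15)
  idx <- utils::combn(fams, 2)
  tm <- tm_score_table(idx[1, ], idx[2, ], runif(ncol(idx)))
  labs <- label_pairs_by_structure(fams, tm)
  expect_equal(nrow(labs), ncol(idx))
  expect_true(all(labs$label %in% c("positive", "negative", "ignored")))
  key <- paste(labs$fam_i, labs$fam_j)
  sc <- tm$tm_score[match(key, paste(tm$family_i, tm$family_j))]
  expect_equal(labs$label == "positive", sc >= 0.5)
  expect_equal(labs$label == "negative", sc < 0.17)
})

test_that("sensitivity curve reproduces the enumeration example", {
  df <- data.frame(fam_i = letters[1:5], fam_j = LETTERS[1:5],
                   score = c(5, 4, 3, 2, 1),
                   stringsAsFactors = FALSE)
  labels <- data.frame(fam_i = df$fam_i, fam_j = df$fam_j,
                       label = c("positive", "positive", "negative",
                                 "positive", "negative"))
  curve <- sensitivity_curve(df, labels)
  expect_equal(curve$fp, c(0, 0, 1, 1, 2))
  expect_equal(curve$tp, c(1, 2, 2, 3, 3))
  expect_equal(tp_at_fp(curve, 1), 3)
  expect_equal(tp_at_fp(curve, 0), 2)
  expect_equal(tp_at_fp(curve, 5), 3)      # k >= total negatives
  # perfect and inverted rankings
  perfect <- sensitivity_curve(
    transform(df, score = ifelse(labels$label == "positive", 10, 1)), labels)
  expect_equal(tp_at_fp(perfect, 0), 3)
  inverted <- sensitivity_curve(
    transform(df, score = ifelse(labels$label == "positive", 1, 10)), labels)
  expect_equal(tp_at_fp(inverted, 0), 0)
  expect_error(sensitivity_curve(df, transform(labels, label = "positive")),
               class = "famsim_error_degenerate_labels")
})

test_that("threshold_at_fp and threshold_at_fdr follow their prefix rules", {
  df <- data.frame(fam_i = c("a", "b", "c"), fam_j = c("x", "y", "z"),
                   score = c(3, 2, 1))
  mk <- function(l) data.frame(fam_i = df$fam_i, fam_j = df$fam_j, label = l)
  pnp <- sensitivity_curve(df, mk(c("positive", "negative", "positive")))
  expect_equal(threshold_at_fp(pnp, 1), 1)
  expect_equal(threshold_at_fp(pnp, 0), 3)
  single <- sensitivity_curve(
    data.frame(fam_i = c("a", "b"), fam_j = c("x", "y"), score = c(2, 1)),
    data.frame(fam_i = c("a", "b"), fam_j = c("x", "y"),
               label = c("positive", "negative")))
  expect_equal(threshold_at_fp(single, 0), 2)

  ppn <- sensitivity_curve(df, mk(c("positive", "positive", "negative")))
  expect_equal(threshold_at_fdr(ppn, 40), 1)   # FDR 1/3 at the full prefix
  expect_equal(threshold_at_fdr(ppn, 0), 2)    # longest clean prefix
  expect_equal(threshold_at_fdr(ppn, 100), 1)  # minimum score
  npp <- sensitivity_curve(df, mk(c("negative", "positive", "positive")))
  expect_error(threshold_at_fdr(npp, 10), class = "famsim_error_no_prefix")
})

test_that("fdr_at_counts is the percentage FP/(FP+TP)", {
  expect_equal(fdr_at_counts(0, 5), 0)
  expect_equal(fdr_at_counts(50, 50), 50)
  expect_error(fdr_at_counts(0, 0), class = "famsim_error_empty_counts")
})

test_that("roc_auc equals the pairwise-comparison probability", {
  df <- data.frame(fam_i = letters[1:4], fam_j = LETTERS[1:4],
                   score = c(4, 3, 2, 1))
  lab <- function(l) data.frame(fam_i = df$fam_i, fam_j = df$fam_j, label = l)
  expect_equal(roc_auc(df, lab(c("positive", "positive", "negative",
                                 "negative"))), 1)
  tied <- transform(df, score = 1)
  expect_equal(roc_auc(tied, lab(c("positive", "negative", "positive",
                                   "negative"))), 0.5)
})

test_that("curve statistics match enumeration oracles on random instances", {
  set.seed(17)
  for (trial in 1:40) {
    df <- random_pair_instance(sample(4:12, 1))
    curve <- sensitivity_curve(df[, 1:3], df[, c(1, 2, 4)])
    for (k in c(0L, 1L, 3L)) {
      expect_equal(tp_at_fp(curve, k), oracle_tp_at_fp(df, k))
      want_th <- oracle_threshold_at_fp(df, k)
      if (is.na(want_th)) {
        expect_error(threshold_at_fp(curve, k),
                     class = "famsim_error_no_prefix")
      } else {
        expect_equal(threshold_at_fp(curve, k), want_th)
      }
    }
    expect_equal(roc_auc(df[, 1:3], df[, c(1, 2, 4)]), oracle_roc_auc(df),
                 tolerance = 1e-12)
    want <- oracle_threshold_at_fdr(df, 30)
    if (is.na(want)) {
      expect_error(threshold_at_fdr(curve, 30),
                   class = "famsim_error_no_prefix")
    } else {
      expect_equal(threshold_at_fdr(curve, 30), want)
    }
  }
})

test_that("tp_at_fp is nondecreasing in k", {
  set.seed(19)
  df <- random_pair_instance(10)
  curve <- sensitivity_curve(df[, 1:3], df[, c(1, 2, 4)])
  tps <- vapply(0:15, function(k) tp_at_fp(curve, k), numeric(1))
  expect_true(all(diff(tps) >= 0))
})

test_that("select_best_source picks the highest TP@kFP, first on ties", {
  set.seed(23)
  fams <- sprintf("F%02d", 1:12)
  cm <- clan_map(fams, rep(c("CL1", "CL2", "CL3"), each = 4))
  labels <- label_pairs_by_clan(fams, cm, "conservative")
  truth <- matrix(0, 12, 12, dimnames = list(fams, fams))
  for (cl in split(fams, rep(1:3, each = 4))) truth[cl, cl] <- 1
  mk <- function(noise_sd) {
    m <- truth + matrix(rnorm(144, sd = noise_sd), 12, 12)
    m <- (m + t(m)) / 2; diag(m) <- NA
    structure(list(family = fams, matrix = m), class = "final_scores")
  }
  graded <- lapply(c(0.05, 0.4, 1.2, 3), mk)
  res <- select_best_source(graded, labels, k = 3)
  expect_equal(res$best, 1L)
  expect_true(all(diff(res$table$tp_at_k) <= 0))
  same <- select_best_source(list(graded[[2]], graded[[2]]), labels, k = 3)
  expect_equal(same$best, 1L)
  expect_error(select_best_source(list(), labels),
               class = "famsim_error_empty_input")
})
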