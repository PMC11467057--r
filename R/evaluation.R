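# Evaluation against clan or structure ground truth
#
# Family-pair classification: every unordered pair of families is positive,
# negative or ignored; the final score ranks pairs, and performance is read
# off the sensitivity curve — chiefly TP@kFP, the number of true positives
# accumulated before more than k false positives occur. Ignored pairs
# (self-pairs, clanless pairs under the conservative definition, TM scores
# in the twilight zone) never enter the ranking.

#' Label family pairs from clan membership
#'
#' Positive iff both families share a clan. Conservative mode: negative only
#' if both families have (different) clans, ignored if either is clanless.
#' Liberal mode: negative iff not positive.
#'
#' @param families character vector of families under evaluation
#' @param cm a `clan_map` covering all of them
#' @param mode "conservative" or "liberal"
#' @return a `pair_labels` data.frame: fam_i, fam_j (i < j), label
#' @export
label_pairs_by_clan <- function(families, cm,
                                mode = c("conservative", "liberal")) {
  mode <- match.arg(mode)
  families <- sort(unique(families))
  clans <- clan_of(cm, families)
  idx <- utils::combn(seq_along(families), 2L)
  ci <- clans[idx[1L, ]]; cj <- clans[idx[2L, ]]
  pos <- !is.na(ci) & !is.na(cj) & ci == cj
  label <- if (mode == "conservative") {
    ifelse(pos, "positive",
           ifelse(!is.na(ci) & !is.na(cj), "negative", "ignored"))
  } else {
    ifelse(pos, "positive", "negative")
  }
  structure(data.frame(fam_i = families[idx[1L, ]],
                       fam_j = families[idx[2L, ]],
                       label = label, stringsAsFactors = FALSE),
            mode = paste0("clan_", mode),
            class = c("pair_labels", "data.frame"))
}

#' Structure-benchmark thresholds
#'
#' @param pos_th TM score at or above which a pair is a ground-truth
#'   positive (default 0.5)
#' @param neg_th TM score strictly below which a pair is a ground-truth
#'   negative (default 0.17, the expected score of two random structures)
#' @export
benchmark_config <- function(pos_th = 0.5, neg_th = 0.17) {
  if (!(neg_th >= 0 && neg_th < pos_th && pos_th <= 1)) {
    famsim_stop("invalid_config", "need 0 <= neg_th < pos_th <= 1")
  }
  structure(list(pos_th = pos_th, neg_th = neg_th),
            class = "benchmark_config")
}

#' Label family pairs from a TM-score table
#'
#' Positive iff tm >= pos_th; negative iff tm < neg_th; ignored when the
#' score falls between the thresholds, when the pair is absent from the
#' table, or when either family lacks a structural model.
#'
#' @param families families under evaluation
#' @param tm a `tm_score_table`
#' @param config a [benchmark_config()]
#' @param families_with_models families that have a structural model
#'   (default: all of `families`)
#' @return a `pair_labels` data.frame
#' @export
label_pairs_by_structure <- function(families, tm,
                                     config = benchmark_config(),
                                     families_with_models = families) {
  families <- sort(unique(families))
  idx <- utils::combn(families, 2L)
  key <- paste(idx[1L, ], idx[2L, ], sep = "\r")
  tmkey <- paste(tm$family_i, tm$family_j, sep = "\r")
  score <- tm$tm_score[match(key, tmkey)]
  modeled <- idx[1L, ] %in% families_with_models &
             idx[2L, ] %in% families_with_models
  label <- rep("ignored", length(key))
  label[modeled & !is.na(score) & score >= config$pos_th] <- "positive"
  label[modeled & !is.na(score) & score < config$neg_th] <- "negative"
  structure(data.frame(fam_i = idx[1L, ], fam_j = idx[2L, ], label = label,
                       stringsAsFactors = FALSE),
            mode = "structure",
            class = c("pair_labels", "data.frame"))
}

#' Sensitivity curve: cumulative TP/FP down the score ranking
#'
#' Non-ignored pairs are sorted by score descending; ties are broken by
#' (fam_i, fam_j) lexicographically for determinism, and each run of equal
#' scores shares a `tie_block` id so tie-straddling cutoffs can be detected.
#'
#' @param scores a `final_scores` object (or any symmetric score matrix
#'   wrapped as list(matrix = ...)); alternatively a data.frame with columns
#'   fam_i, fam_j, score
#' @param labels a `pair_labels` data.frame covering the scored families
#' @return a `sensitivity_curve` object
#' @export
sensitivity_curve <- function(scores, labels) {
  ps <- if (is.data.frame(scores)) scores else pair_scores(scores)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  lab <- labels$label[match(key(ps$fam_i, ps$fam_j),
                            key(labels$fam_i, labels$fam_j))]
  if (anyNA(lab)) {
    famsim_stop("unlabeled_pair", sprintf(
      "%d scored pair(s) have no label", sum(is.na(lab))))
  }
  use <- lab != "ignored"
  ps <- ps[use, , drop = FALSE]; lab <- lab[use]
  if (!any(lab == "positive") || !any(lab == "negative")) {
    famsim_stop("degenerate_labels",
                "need at least one positive and one negative pair")
  }
  ord <- order(-ps$score, ps$fam_i, ps$fam_j)
  ps <- ps[ord, , drop = FALSE]; lab <- lab[ord]
  tie_block <- cumsum(c(1L, diff(ps$score) != 0))
  structure(list(rank = seq_along(lab), score = ps$score,
                 fp = cumsum(lab == "negative"),
                 tp = cumsum(lab == "positive"),
                 tie_block = tie_block,
                 fam_i = ps$fam_i, fam_j = ps$fam_j),
            class = "sensitivity_curve")
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  n <- length(x$rank)
  cat(sprintf("<sensitivity_curve: %d pairs, %d TP, %d FP total>\n",
              n, x$tp[n], x$fp[n]))
  invisible(x)
}

#' True positives at k false positives
#'
#' Maximum cumulative TP over all ranking prefixes with at most k false
#' positives (equal to total TP when total FP <= k).
#'
#' @param curve a `sensitivity_curve`
#' @param k allowed false positives (default 100)
#' @export
tp_at_fp <- function(curve, k = 100L) {
  ok <- curve$fp <= k
  if (!any(ok)) return(0L)
  max(curve$tp[ok])
}

#' Score threshold at k false positives
#'
#' The score of the last pair in the prefix realizing [tp_at_fp()].
#' @param curve a `sensitivity_curve`
#' @param k allowed false positives
#' @export
threshold_at_fp <- function(curve, k = 100L) {
  ok <- which(curve$fp <= k)
  if (!length(ok)) {
    famsim_stop("no_prefix", "the very first pair already exceeds k false positives")
  }
  curve$score[max(ok)]
}

#' False discovery rate from FP/TP counts, as a percentage
#' @param fp,tp counts
#' @return 100 * fp / (fp + tp), rounded to two decimals
#' @export
fdr_at_counts <- function(fp, tp) {
  if (fp + tp == 0) famsim_stop("empty_counts", "fp + tp must be positive")
  round(100 * fp / (fp + tp), 2)
}

#' Score threshold achieving a target FDR
#'
#' Scans prefixes ending at distinct-score boundaries and returns the score
#' of the longest (lowest-scoring) prefix whose FDR is at most the target.
#'
#' @param curve a `sensitivity_curve`
#' @param target_fdr target FDR in percent (e.g. 1 for one percent)
#' @export
threshold_at_fdr <- function(curve, target_fdr) {
  n <- length(curve$rank)
  block_end <- which(c(curve$tie_block[-1L] != curve$tie_block[-n], TRUE))
  fdr <- 100 * curve$fp[block_end] / (curve$fp[block_end] + curve$tp[block_end])
  ok <- block_end[!is.nan(fdr) & fdr <= target_fdr]
  if (!length(ok)) {
    famsim_stop("no_prefix", sprintf("no prefix achieves FDR <= %g%%", target_fdr))
  }
  curve$score[max(ok)]
}

#' ROC AUC of the pair scores against the labels
#'
#' Equals the probability that a random positive pair outscores a random
#' negative pair, ties counting one half (Mann-Whitney statistic).
#'
#' @param scores as in [sensitivity_curve()]
#' @param labels a `pair_labels` data.frame
#' @export
roc_auc <- function(scores, labels) {
  ps <- if (is.data.frame(scores)) scores else pair_scores(scores)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  lab <- labels$label[match(key(ps$fam_i, ps$fam_j),
                            key(labels$fam_i, labels$fam_j))]
  pos <- ps$score[!is.na(lab) & lab == "positive"]
  neg <- ps$score[!is.na(lab) & lab == "negative"]
  if (!length(pos) || !length(neg)) {
    famsim_stop("degenerate_labels",
                "need at least one positive and one negative pair")
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Select the best score source by TP@kFP
#'
#' @param score_list list of `final_scores` objects (e.g. one per ensemble
#'   member)
#' @param labels a `pair_labels` data.frame
#' @param k allowed false positives (default 100)
#' @return list(best = index of the winner, first index on ties;
#'   table = data.frame(source, tp_at_k))
#' @export
select_best_source <- function(score_list, labels, k = 100L) {
  if (!length(score_list)) {
    famsim_stop("empty_input", "score_list must be non-empty")
  }
  tps <- vapply(score_list, function(s) {
    as.integer(tp_at_fp(sensitivity_curve(s, labels), k))
  }, integer(1))
  list(best = which.max(tps),
       table = data.frame(source = seq_along(tps), tp_at_k = tps))
}
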