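# Independent brute-force oracles. These deliberately avoid the vectorized
# tricks used by the implementation: plain position-by-position scans and
# O(n^2) recounts, so they can serve as ground truth.

# per-column run-length scan for domain calling
oracle_call_domains <- function(probs, min_length, prob_threshold,
                                classes = colnames(probs)) {
  out <- list()
  for (ci in seq_len(ncol(probs))) {
    run_start <- NA_integer_
    for (pos in seq_len(nrow(probs) + 1L)) {
      above <- pos <= nrow(probs) && probs[pos, ci] > prob_threshold
      if (above && is.na(run_start)) run_start <- pos
      if (!above && !is.na(run_start)) {
        run_len <- pos - run_start
        if (run_len >= min_length) {
          out[[length(out) + 1L]] <- data.frame(
            family = classes[ci], start = run_start - 1L, end = pos - 1L,
            mean_probability = mean(probs[run_start:(pos - 1L), ci]),
            stringsAsFactors = FALSE)
        }
        run_start <- NA_integer_
      }
    }
  }
  if (!length(out)) {
    return(data.frame(family = character(0), start = integer(0),
                      end = integer(0), mean_probability = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$family, res$start), , drop = FALSE]
}

# deterministic pair ordering shared by the enumeration oracles
oracle_order <- function(df) {
  df[order(-df$score, df$fam_i, df$fam_j), , drop = FALSE]
}

# prefix-by-prefix recount of TP at <= k FP
oracle_tp_at_fp <- function(df, k) {
  df <- oracle_order(df[df$label != "ignored", , drop = FALSE])
  best <- 0L
  for (m in seq_len(nrow(df))) {
    fp <- sum(df$label[1:m] == "negative")
    tp <- sum(df$label[1:m] == "positive")
    if (fp <= k && tp > best) best <- tp
  }
  best
}

oracle_threshold_at_fp <- function(df, k) {
  df <- oracle_order(df[df$label != "ignored", , drop = FALSE])
  last <- NA_real_
  for (m in seq_len(nrow(df))) {
    if (sum(df$label[1:m] == "negative") <= k) last <- df$score[m]
  }
  last
}

# lowest prefix-end score (over distinct-score boundaries) with FDR <= target
oracle_threshold_at_fdr <- function(df, target_pct) {
  df <- oracle_order(df[df$label != "ignored", , drop = FALSE])
  best <- NA_real_
  for (m in seq_len(nrow(df))) {
    if (m < nrow(df) && df$score[m + 1L] == df$score[m]) next  # inside a tie
    fp <- sum(df$label[1:m] == "negative")
    tp <- sum(df$label[1:m] == "positive")
    if (100 * fp / (fp + tp) <= target_pct) best <- df$score[m]
  }
  best
}

# all positive-negative comparisons, ties half
oracle_roc_auc <- function(df) {
  pos <- df$score[df$label == "positive"]
  neg <- df$score[df$label == "negative"]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# random labeled pair-score instance for the evaluation oracles
random_pair_instance <- function(n_fam, tie_prob = 0.3) {
  fams <- sprintf("F%02d", seq_len(n_fam))
  idx <- utils::combn(fams, 2L)
  n <- ncol(idx)
  score <- round(stats::runif(n), if (stats::runif(1) < tie_prob) 1L else 6L)
  label <- sample(c("positive", "negative", "ignored"), n, replace = TRUE,
                  prob = c(0.35, 0.45, 0.2))
  # guarantee the degenerate-label precondition
  label[sample(n, 1L)] <- "positive"
  rest <- setdiff(seq_len(n), which(label == "positive"))
  label[rest[sample.int(length(rest), 1L)]] <- "negative"
  data.frame(fam_i = idx[1L, ], fam_j = idx[2L, ], score = score,
             label = label, stringsAsFactors = FALSE)
}

# small family_embeddings object from a plain matrix
fe_from_matrix <- function(m, fams = sprintf("PF%05d", seq_len(nrow(m)))) {
  famsim:::new_family_embeddings(fams, m, rep(1L, nrow(m)))
}

# random valid domain-call table
random_calls <- function(n) {
  start <- sample(0:400, n, replace = TRUE)
  domain_calls(sequence_id = sample(sprintf("seq%02d", 1:8), n, TRUE),
               family = sample(sprintf("PF%05d", 1:12), n, TRUE),
               start = start,
               end = start + sample(20:120, n, TRUE),
               mean_probability = signif(stats::runif(n, 0.03, 1), 6))
}
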