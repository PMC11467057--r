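# Domain calling
#
# A domain call is a maximal run of consecutive residues whose probability
# for one family class stays strictly above `prob_threshold`, kept only if
# the run is at least `min_length` residues long. Calling is per class:
# spans for different families may overlap (this is exactly the mechanism by
# which nested domains produce shared residues downstream).

#' Calling configuration
#'
#' @param min_length minimum span length in residues (inclusive); default 20
#' @param prob_threshold strict lower bound on per-residue probability;
#'   default 0.025
#' @export
calling_config <- function(min_length = 20L, prob_threshold = 0.025) {
  min_length <- as.integer(min_length)
  if (is.na(min_length) || min_length < 1L) {
    famsim_stop("invalid_config", "min_length must be >= 1")
  }
  if (prob_threshold < 0 || prob_threshold >= 1) {
    famsim_stop("invalid_config", "prob_threshold must be in [0, 1)")
  }
  structure(list(min_length = min_length, prob_threshold = prob_threshold),
            class = "calling_config")
}

#' Call domains from a per-residue probability matrix
#'
#' For each class column independently, every maximal run of positions with
#' probability strictly above the threshold and length at least `min_length`
#' yields exactly one call.
#'
#' @param probs L x C matrix of probabilities in \[0, 1\]; column names (or
#'   `classes`) give the family accessions
#' @param sequence_id id recorded on the emitted calls
#' @param config a [calling_config()]
#' @param classes optional character vector overriding `colnames(probs)`
#' @return a [domain_calls()] table (0-based half-open spans), sorted by
#'   family then start
#' @export
call_domains <- function(probs, sequence_id = "seq",
                         config = calling_config(), classes = NULL) {
  probs <- as.matrix(probs)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    famsim_stop("probability_range", sprintf(
      "sequence '%s': probabilities must lie in [0, 1]", sequence_id))
  }
  if (is.null(classes)) classes <- colnames(probs)
  if (is.null(classes)) classes <- as.character(seq_len(ncol(probs)))
  out_fam <- character(0); out_s <- integer(0); out_e <- integer(0)
  out_p <- numeric(0)
  for (c_idx in seq_len(ncol(probs))) {
    p <- probs[, c_idx]
    r <- rle(p > config$prob_threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= config$min_length
    for (i in which(keep)) {
      out_fam <- c(out_fam, classes[c_idx])
      out_s <- c(out_s, starts[i] - 1L)          # to 0-based half-open
      out_e <- c(out_e, ends[i])
      out_p <- c(out_p, mean(p[starts[i]:ends[i]]))
    }
  }
  calls <- domain_calls(rep(sequence_id, length(out_fam)), out_fam,
                        out_s, out_e, out_p)
  calls[order(calls$family, calls$start), , drop = FALSE]
}

#' Call domains for every sequence in a probability store
#'
#' @param store a `probability_store`
#' @param config a [calling_config()]
#' @return a combined [domain_calls()] table
#' @export
call_domains_store <- function(store, config = calling_config()) {
  classes <- attr(store, "classes")
  parts <- lapply(names(store), function(sid) {
    call_domains(store[[sid]], sequence_id = sid, config = config,
                 classes = classes)
  })
  res <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(res)) res <- domain_calls()
  structure(res, class = c("domain_calls", "data.frame"))
}

#' Midpoint-overlap test between a predicted and a reference span
#'
#' True iff the overlap covers more than half of the predicted span OR more
#' than half of the reference span (0-based half-open spans).
#'
#' @param pred_start,pred_end predicted span
#' @param ref_start,ref_end reference span
#' @return logical (vectorized)
#' @export
midpoint_overlap <- function(pred_start, pred_end, ref_start, ref_end) {
  if (any(pred_end <= pred_start) || any(ref_end <= ref_start)) {
    famsim_stop("invalid_span", "spans must satisfy end > start")
  }
  ov <- pmax(0L, pmin(pred_end, ref_end) - pmax(pred_start, ref_start))
  ov / (pred_end - pred_start) > 0.5 | ov / (ref_end - ref_start) > 0.5
}

#' Filter calls against a reference domain table
#'
#' `mode = "all"` keeps everything (the best-performing configuration);
#' `"seed_overlap"` / `"full_overlap"` keep a call only if some reference
#' row from the corresponding alignment source, on the same sequence and
#' with the same family, passes [midpoint_overlap()].
#'
#' @param calls a [domain_calls()] table
#' @param reference reference table from [read_reference_domains()]
#'   (required for the overlap modes)
#' @param mode one of "all", "seed_overlap", "full_overlap"
#' @export
filter_calls <- function(calls, reference = NULL,
                         mode = c("all", "seed_overlap", "full_overlap")) {
  mode <- match.arg(mode)
  if (mode == "all") return(calls)
  if (is.null(reference)) {
    famsim_stop("missing_reference",
                sprintf("mode '%s' requires a reference domain table", mode))
  }
  src <- if (mode == "seed_overlap") "SEED" else "FULL"
  ref <- reference[reference$source == src, , drop = FALSE]
  keep <- vapply(seq_len(nrow(calls)), function(i) {
    cand <- ref[ref$sequence_id == calls$sequence_id[i] &
                  ref$family == calls$family[i], , drop = FALSE]
    nrow(cand) > 0 && any(midpoint_overlap(calls$start[i], calls$end[i],
                                           cand$start, cand$end))
  }, logical(1))
  calls[keep, , drop = FALSE]
}

#' Family co-occurrence diagnostics
#'
#' For every unordered pair of families counts, across sequences: how often
#' both are called on the same sequence, how often their calls overlap by at
#' least one residue (the nested-domain signature), and how often they sit
#' within `gap` residues of each other without overlapping (the
#' adjacent-domain signature). Diagnostic only; no correction is applied to
#' the scores.
#'
#' @param calls a [domain_calls()] table
#' @param gap adjacency gap in residues (default 30)
#' @return data.frame with columns family_i, family_j (i < j),
#'   n_same_sequence, n_residue_overlap, n_adjacent
#' @export
cooccurrence_stats <- function(calls, gap = 30L) {
  acc <- new.env(parent = emptyenv())
  bump <- function(a, b, field) {
    key <- paste(min(a, b), max(a, b), sep = "\r")
    cur <- if (is.null(acc[[key]])) c(same = 0L, overlap = 0L, adjacent = 0L)
           else acc[[key]]
    cur[[field]] <- cur[[field]] + 1L
    acc[[key]] <- cur
  }
  for (sid in unique(calls$sequence_id)) {
    sc <- calls[calls$sequence_id == sid, , drop = FALSE]
    fams <- unique(sc$family)
    if (length(fams) < 2L) next
    for (i in seq_len(length(fams) - 1L)) for (j in (i + 1L):length(fams)) {
      a <- sc[sc$family == fams[i], , drop = FALSE]
      b <- sc[sc$family == fams[j], , drop = FALSE]
      bump(fams[i], fams[j], "same")
      pairs <- expand.grid(ia = seq_len(nrow(a)), ib = seq_len(nrow(b)))
      ov <- pmin(a$end[pairs$ia], b$end[pairs$ib]) -
            pmax(a$start[pairs$ia], b$start[pairs$ib])
      if (any(ov >= 1L)) bump(fams[i], fams[j], "overlap")
      gaps <- ifelse(ov >= 1L, Inf,
                     pmax(a$start[pairs$ia], b$start[pairs$ib]) -
                       pmin(a$end[pairs$ia], b$end[pairs$ib]))
      if (any(gaps <= gap & gaps >= 0)) bump(fams[i], fams[j], "adjacent")
    }
  }
  keys <- ls(acc)
  if (!length(keys)) {
    return(data.frame(family_i = character(0), family_j = character(0),
                      n_same_sequence = integer(0),
                      n_residue_overlap = integer(0),
                      n_adjacent = integer(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  counts <- do.call(rbind, lapply(keys, function(k) acc[[k]]))
  out <- data.frame(family_i = vapply(parts, `[[`, character(1), 1L),
                    family_j = vapply(parts, `[[`, character(1), 2L),
                    n_same_sequence = counts[, "same"],
                    n_residue_overlap = counts[, "overlap"],
                    n_adjacent = counts[, "adjacent"],
                    stringsAsFactors = FALSE)
  out[order(out$family_i, out$family_j), , drop = FALSE]
}
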