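# Synthetic corpus generator
#
# A corpus is a stated world with planted structure:
#   * each clan k has a direction c_k, each family f a private direction
#     v_f; family f in clan k points along u_f = alpha*c_k + beta*v_f, so
#     clan-mates share a strong common component and the clan signal is
#     recoverable from embeddings;
#   * "sticky" families (the coiled-coil / disorder analog) are clanless
#     but share a dedicated blob direction with weight `sticky_offset`,
#     giving the whole group mutually inflated raw cosine similarity that
#     per-family z-normalization is expected to neutralize;
#   * each sequence carries one true domain span; residues inside the span
#     point along u_f, smoothed along the length axis with an exponential
#     (AR(1)-shaped, coefficient rho) kernel so adjacent residues are more
#     similar than distant ones and signal leaks a little into flanking
#     context, plus stationary AR(1) noise;
#   * the probability matrix puts the true family's probability around 0.9
#     inside the span and below 0.005 outside;
#   * the TM-score table draws clan-mates around 0.65 and everything else
#     around 0.10, tying the structure benchmark to the planted clans;
#   * failure modes are planted as extra co-occurrence sequences: nested
#     (B's span strictly inside A's), adjacent (B starts <= gap residues
#     after A ends) and shared-neighbour (X-Z and Y-Z adjacent, X and Y
#     never co-occurring).

#' Synthetic corpus configuration
#'
#' @param n_clans number of clans
#' @param families_per_clan families in each clan
#' @param n_clanless_families extra families with no clan
#' @param sequences_per_family base (solo) sequences per family
#' @param domain_length inclusive range of true domain lengths (residues)
#' @param flank_length inclusive range of flank lengths either side
#' @param embedding_dim D
#' @param alpha clan signal strength
#' @param beta family signal strength
#' @param noise_sd stationary standard deviation of the AR(1) residue noise
#' @param rho AR(1) coefficient / smoothing decay, in \[0, 1)
#' @param sticky_family_count clanless families forming the sticky blob
#' @param sticky_offset weight of the shared sticky-blob direction
#' @param nested_pairs,adjacent_pairs,shared_neighbor_triples failure-mode
#'   scenarios planted at generation time (consume clanless families)
#' @param plant_gap residue gap used when planting adjacent spans
#' @param plant_span_length span length used for planted domains (default
#'   20, the shortest callable span: context leakage is strongest when the
#'   span is short relative to the smoothing kernel)
#' @param plant_sequences co-occurrence sequences per planted scenario
#'   (default 3x `sequences_per_family`, so co-occurrence dominates the
#'   planted families' instances, as in the real failure cases)
#' @param tm_pos,tm_neg mean/sd of TM scores for clan-mates and others
#' @param seed RNG seed; identical seeds give bit-identical corpora
#' @export
corpus_config <- function(n_clans = 4L, families_per_clan = 10L,
                          n_clanless_families = 0L,
                          sequences_per_family = 10L,
                          domain_length = c(30L, 80L),
                          flank_length = c(10L, 30L),
                          embedding_dim = 32L,
                          alpha = 1.2, beta = 0.5,
                          noise_sd = 0.3, rho = 0.9,
                          sticky_family_count = 0L, sticky_offset = 1.5,
                          nested_pairs = 0L, adjacent_pairs = 0L,
                          shared_neighbor_triples = 0L,
                          plant_gap = 2L,
                          plant_span_length = 20L,
                          plant_sequences = 3L * sequences_per_family,
                          tm_pos = c(0.65, 0.08), tm_neg = c(0.10, 0.04),
                          seed = 1L) {
  cfg <- list(n_clans = as.integer(n_clans),
              families_per_clan = as.integer(families_per_clan),
              n_clanless_families = as.integer(n_clanless_families),
              sequences_per_family = as.integer(sequences_per_family),
              domain_length = as.integer(domain_length),
              flank_length = as.integer(flank_length),
              embedding_dim = as.integer(embedding_dim),
              alpha = alpha, beta = beta, noise_sd = noise_sd, rho = rho,
              sticky_family_count = as.integer(sticky_family_count),
              sticky_offset = sticky_offset,
              nested_pairs = as.integer(nested_pairs),
              adjacent_pairs = as.integer(adjacent_pairs),
              shared_neighbor_triples = as.integer(shared_neighbor_triples),
              plant_gap = as.integer(plant_gap),
              plant_span_length = as.integer(plant_span_length),
              plant_sequences = as.integer(plant_sequences),
              tm_pos = tm_pos, tm_neg = tm_neg,
              seed = as.integer(seed))
  counts <- c(cfg$n_clans, cfg$families_per_clan, cfg$n_clanless_families,
              cfg$sequences_per_family, cfg$sticky_family_count,
              cfg$nested_pairs, cfg$adjacent_pairs,
              cfg$shared_neighbor_triples)
  if (any(counts < 0L)) famsim_stop("invalid_config", "counts must be >= 0")
  if (cfg$rho < 0 || cfg$rho >= 1) {
    famsim_stop("invalid_config", "rho must be in [0, 1)")
  }
  if (cfg$embedding_dim < 2L) {
    famsim_stop("invalid_config", "embedding_dim must be >= 2")
  }
  needed <- 2L * cfg$nested_pairs + 2L * cfg$adjacent_pairs +
    3L * cfg$shared_neighbor_triples
  if (needed > cfg$n_clanless_families) {
    famsim_stop("invalid_config", sprintf(
      "failure-mode planting needs %d clanless families, config has %d",
      needed, cfg$n_clanless_families))
  }
  structure(cfg, class = "corpus_config")
}

random_unit <- function(d) {
  v <- stats::rnorm(d)
  v / sqrt(sum(v^2))
}

# exponential smoothing along rows with kernel rho^|d|, normalized to unit
# mass; emulates the receptive-field smoothness of convolutional embeddings
smooth_ar1 <- function(mat, rho) {
  if (rho == 0 || nrow(mat) == 1L) return(mat)
  fwd <- apply(mat, 2L, function(x) {
    as.numeric(stats::filter(x, rho, method = "recursive"))
  })
  bwd <- apply(mat[rev(seq_len(nrow(mat))), , drop = FALSE], 2L, function(x) {
    as.numeric(stats::filter(x, rho, method = "recursive"))
  })
  bwd <- bwd[rev(seq_len(nrow(mat))), , drop = FALSE]
  (fwd + bwd - mat) * (1 - rho) / (1 + rho)
}

# stationary AR(1) noise matrix, per-column sd `sd`
ar1_noise <- function(l, d, rho, sd) {
  n <- matrix(0, l, d)
  n[1L, ] <- stats::rnorm(d, sd = sd)
  if (l > 1L) {
    innov_sd <- sd * sqrt(1 - rho^2)
    for (t in 2:l) n[t, ] <- rho * n[t - 1L, ] + stats::rnorm(d, sd = innov_sd)
  }
  n
}

# build one sequence from a span layout: spans is a data.frame with columns
# family, start, end (0-based half-open). Returns list(emb, probs, spans).
build_sequence <- function(spans, len, directions, classes, cfg) {
  d <- cfg$embedding_dim
  signal <- matrix(0, len, d)
  probs <- matrix(stats::runif(len * length(classes), 0, 0.005),
                  len, length(classes))
  for (i in seq_len(nrow(spans))) {
    rows <- (spans$start[i] + 1L):spans$end[i]
    # overlapping spans add their directions: residues carrying two family
    # labels contribute to both families' averages downstream
    signal[rows, ] <- signal[rows, ] +
      matrix(directions[spans$family[i], ], length(rows), d, byrow = TRUE)
    probs[rows, match(spans$family[i], classes)] <- stats::runif(
      length(rows), 0.85, 0.95)
  }
  emb <- smooth_ar1(signal, cfg$rho) + ar1_noise(len, d, cfg$rho, cfg$noise_sd)
  list(emb = emb, probs = probs)
}

rint <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(range[1L]:range[2L], n, replace = TRUE)
}

#' Generate a complete synthetic corpus
#'
#' @param cfg a [corpus_config()]
#' @return a `famsim_corpus`: list with `embeddings` (embedding_store),
#'   `probabilities` (probability_store), `clan_map`, `tm` (tm_score_table)
#'   and `truth` (true spans, family table with sticky flags, family
#'   directions, planted failure-mode list, the config)
#' @export
generate_corpus <- function(cfg = corpus_config()) {
  stopifnot(inherits(cfg, "corpus_config"))
  set.seed(cfg$seed)
  n_clan_fams <- cfg$n_clans * cfg$families_per_clan
  n_fams <- n_clan_fams + cfg$n_clanless_families + cfg$sticky_family_count
  fams <- sprintf("PF%05d", seq_len(n_fams))
  clans <- c(rep(sprintf("CL%04d", seq_len(cfg$n_clans)),
                 each = cfg$families_per_clan),
             rep(NA_character_,
                 cfg$n_clanless_families + cfg$sticky_family_count))
  sticky <- c(rep(FALSE, n_clan_fams + cfg$n_clanless_families),
              rep(TRUE, cfg$sticky_family_count))

  d <- cfg$embedding_dim
  clan_dirs <- t(vapply(seq_len(cfg$n_clans), function(i) random_unit(d),
                        numeric(d)))
  blob_dir <- random_unit(d)
  directions <- matrix(0, n_fams, d, dimnames = list(fams, NULL))
  for (i in seq_len(n_fams)) {
    own <- cfg$beta * random_unit(d)
    core <- if (!is.na(clans[i])) {
      cfg$alpha * clan_dirs[match(clans[i], sprintf("CL%04d",
                                                    seq_len(cfg$n_clans))), ]
    } else if (sticky[i]) {
      cfg$sticky_offset * blob_dir
    } else {
      cfg$alpha * random_unit(d)  # clanless: private core direction
    }
    directions[i, ] <- core + own
  }

  emb <- list(); prob <- list()
  span_rows <- list()
  for (i in seq_len(n_fams)) {
    for (s in seq_len(cfg$sequences_per_family)) {
      sid <- sprintf("%s_seq%03d", fams[i], s)
      fl <- rint(2L, cfg$flank_length)
      dl <- rint(1L, cfg$domain_length)
      len <- fl[1L] + dl + fl[2L]
      spans <- data.frame(family = fams[i], start = fl[1L],
                          end = fl[1L] + dl, stringsAsFactors = FALSE)
      sq <- build_sequence(spans, len, directions, fams, cfg)
      emb[[sid]] <- sq$emb; prob[[sid]] <- sq$probs
      span_rows[[sid]] <- cbind(sequence_id = sid, spans)
    }
  }

  cm <- clan_map(fams, clans)
  pairs <- utils::combn(fams, 2L)
  mates <- clans[match(pairs[1L, ], fams)] == clans[match(pairs[2L, ], fams)]
  mates[is.na(mates)] <- FALSE
  mu <- ifelse(mates, cfg$tm_pos[1L], cfg$tm_neg[1L])
  sdv <- ifelse(mates, cfg$tm_pos[2L], cfg$tm_neg[2L])
  tm <- tm_score_table(pairs[1L, ], pairs[2L, ],
                       pmin(1, pmax(0, stats::rnorm(ncol(pairs), mu, sdv))))

  corpus <- structure(
    list(embeddings = embedding_store(emb),
         probabilities = probability_store(prob, classes = fams),
         clan_map = cm, tm = tm,
         truth = list(
           spans = do.call(rbind, c(span_rows, list(make.row.names = FALSE))),
           families = data.frame(family = fams, clan = clans,
                                 sticky = sticky, stringsAsFactors = FALSE),
           directions = directions,
           planted = data.frame(kind = character(0), family_a = character(0),
                                family_b = character(0),
                                via = character(0),
                                stringsAsFactors = FALSE),
           config = cfg)),
    class = "famsim_corpus")

  # auto-plant failure modes on the leading clanless families
  clanless <- fams[is.na(clans) & !sticky]
  take <- function(n) {
    out <- clanless[seq_len(n)]
    clanless <<- clanless[-seq_len(n)]
    out
  }
  for (i in seq_len(cfg$nested_pairs)) {
    ab <- take(2L)
    corpus <- plant_nested_pair(corpus, ab[1L], ab[2L], seed = NULL)
  }
  for (i in seq_len(cfg$adjacent_pairs)) {
    ab <- take(2L)
    corpus <- plant_adjacent_pair(corpus, ab[1L], ab[2L], seed = NULL)
  }
  for (i in seq_len(cfg$shared_neighbor_triples)) {
    xyz <- take(3L)
    corpus <- plant_shared_neighbor(corpus, xyz[1L], xyz[2L], xyz[3L],
                                    seed = NULL)
  }
  corpus
}

#' @export
print.famsim_corpus <- function(x, ...) {
  cat(sprintf("<famsim_corpus: %d families, %d sequences, D = %d>\n",
              nrow(x$truth$families), length(x$embeddings),
              x$truth$config$embedding_dim))
  invisible(x)
}

check_in_corpus <- function(corpus, fams) {
  missing <- setdiff(fams, corpus$truth$families$family)
  if (length(missing)) {
    famsim_stop("unknown_family", sprintf(
      "families not in corpus: %s", paste(missing, collapse = ", ")))
  }
}

# shared machinery: add `n` co-occurrence sequences laid out by layout_fn,
# a function(index) -> list(spans = data.frame(family, start, end), len)
add_planted_sequences <- function(corpus, tag, n, layout_fn, seed) {
  cfg <- corpus$truth$config
  if (is.null(seed)) {
    # continue deterministically from the corpus seed
    seed <- cfg$seed + 7919L * (nrow(corpus$truth$planted) + 1L)
  }
  set.seed(as.integer(seed))
  emb <- unclass(corpus$embeddings)
  prob <- unclass(corpus$probabilities)
  spans_acc <- list()
  for (s in seq_len(n)) {
    lay <- layout_fn(s)
    sid <- sprintf("%s_seq%03d", tag, s)
    sq <- build_sequence(lay$spans, lay$len, corpus$truth$directions,
                         attr(corpus$probabilities, "classes"), cfg)
    emb[[sid]] <- sq$emb; prob[[sid]] <- sq$probs
    spans_acc[[sid]] <- cbind(sequence_id = sid, lay$spans)
  }
  corpus$embeddings <- embedding_store(emb)
  corpus$probabilities <- probability_store(
    prob, classes = attr(corpus$probabilities, "classes"))
  corpus$truth$spans <- rbind(corpus$truth$spans,
                              do.call(rbind, c(spans_acc,
                                               list(make.row.names = FALSE))))
  corpus
}

#' Plant a nested-domain failure scenario
#'
#' Adds co-occurrence sequences in which family B's span lies strictly
#' inside family A's span, so the overlapping residues carry both labels
#' and contaminate both families' embeddings.
#'
#' @param corpus a `famsim_corpus`
#' @param fam_a outer family
#' @param fam_b inner (nested) family
#' @param n_sequences co-occurrence sequences to add (default
#'   `plant_sequences` from the config)
#' @param seed RNG seed (default: derived from the corpus seed)
#' @export
plant_nested_pair <- function(corpus, fam_a, fam_b,
                              n_sequences = corpus$truth$config$plant_sequences,
                              seed = NULL) {
  check_in_corpus(corpus, c(fam_a, fam_b))
  cfg <- corpus$truth$config
  corpus <- add_planted_sequences(
    corpus, sprintf("nest_%s_%s", fam_a, fam_b), n_sequences,
    function(s) {
      inner <- cfg$plant_span_length
      outer <- inner + 2L * 20L
      fl <- rint(2L, cfg$flank_length)
      off <- rint(1L, c(15L, outer - inner - 15L))
      list(spans = data.frame(
             family = c(fam_a, fam_b),
             start = c(fl[1L], fl[1L] + off),
             end = c(fl[1L] + outer, fl[1L] + off + inner),
             stringsAsFactors = FALSE),
           len = fl[1L] + outer + fl[2L])
    }, seed)
  corpus$truth$planted <- rbind(
    corpus$truth$planted,
    data.frame(kind = "nested", family_a = fam_a, family_b = fam_b,
               via = NA_character_, stringsAsFactors = FALSE))
  corpus
}

#' Plant an adjacent-domain failure scenario
#'
#' Adds co-occurrence sequences where family B's span begins at most
#' `plant_gap` residues after family A's span ends; the smoothing kernel
#' leaks each family's signal into the other's span (context leakage).
#'
#' @inheritParams plant_nested_pair
#' @param fam_a,fam_b the two families placed next to each other
#' @export
plant_adjacent_pair <- function(corpus, fam_a, fam_b,
                                n_sequences = corpus$truth$config$plant_sequences,
                                seed = NULL) {
  check_in_corpus(corpus, c(fam_a, fam_b))
  cfg <- corpus$truth$config
  corpus <- add_planted_sequences(
    corpus, sprintf("adj_%s_%s", fam_a, fam_b), n_sequences,
    function(s) {
      dl <- cfg$plant_span_length
      fl <- rint(2L, cfg$flank_length)
      gap <- rint(1L, c(0L, cfg$plant_gap))
      list(spans = data.frame(
             family = c(fam_a, fam_b),
             start = c(fl[1L], fl[1L] + dl + gap),
             end = c(fl[1L] + dl, fl[1L] + dl + gap + dl),
             stringsAsFactors = FALSE),
           len = fl[1L] + 2L * dl + gap + fl[2L])
    }, seed)
  corpus$truth$planted <- rbind(
    corpus$truth$planted,
    data.frame(kind = "adjacent", family_a = fam_a, family_b = fam_b,
               via = NA_character_, stringsAsFactors = FALSE))
  corpus
}

#' Plant a shared-adjacent-domain failure scenario
#'
#' X and Y never co-occur, but each is planted adjacent to the same
#' neighbour Z, so both acquire Z-flavoured context.
#'
#' @inheritParams plant_nested_pair
#' @param fam_x,fam_y the two families that never co-occur
#' @param fam_z the shared neighbour
#' @export
plant_shared_neighbor <- function(corpus, fam_x, fam_y, fam_z,
                                  n_sequences = corpus$truth$config$plant_sequences,
                                  seed = NULL) {
  check_in_corpus(corpus, c(fam_x, fam_y, fam_z))
  corpus <- plant_adjacent_pair(corpus, fam_x, fam_z, n_sequences, seed)
  corpus <- plant_adjacent_pair(corpus, fam_y, fam_z, n_sequences,
                                if (is.null(seed)) NULL else seed + 1L)
  # rewrite the two adjacency entries as one shared-neighbour entry
  n <- nrow(corpus$truth$planted)
  corpus$truth$planted <- rbind(
    corpus$truth$planted[seq_len(n - 2L), , drop = FALSE],
    data.frame(kind = "shared_neighbor", family_a = fam_x, family_b = fam_y,
               via = fam_z, stringsAsFactors = FALSE))
  corpus
}

#' Run the scoring pipeline on a corpus
#'
#' Convenience wrapper: call domains, aggregate embeddings, score.
#'
#' @param corpus a `famsim_corpus`
#' @param config a [calling_config()]
#' @param method final aggregation method
#' @return list(calls, family_embeddings, raw, normed, final)
#' @export
score_corpus <- function(corpus, config = calling_config(),
                         method = "max") {
  calls <- call_domains_store(corpus$probabilities, config)
  fe <- family_embeddings(domain_embeddings(corpus$embeddings, calls))
  raw <- cosine_matrix(fe)
  normed <- normalize_scores(raw)
  final <- aggregate_scores(normed, method)
  list(calls = calls, family_embeddings = fe, raw = raw, normed = normed,
       final = final)
}
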