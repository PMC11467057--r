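# Embedding aggregation
#
# Per-residue embeddings are averaged along the length axis over each called
# span to give a domain embedding; the domain embeddings of all instances of
# a family are averaged (unweighted, one vote per instance regardless of
# span length) to give the family embedding.

#' Domain embedding: mean of per-residue embeddings over a span
#'
#' @param emb L x D matrix of per-residue embeddings for one sequence
#' @param start,end 0-based half-open span within \[0, L)
#' @return numeric D-vector
#' @export
domain_embedding <- function(emb, start, end) {
  emb <- as.matrix(emb)
  if (start < 0L || end > nrow(emb) || end <= start) {
    famsim_stop("invalid_span", sprintf(
      "span [%d, %d) out of bounds for a sequence of length %d",
      start, end, nrow(emb)))
  }
  colMeans(emb[(start + 1L):end, , drop = FALSE])
}

#' Domain embeddings for a whole call set
#'
#' @param store an `embedding_store`
#' @param calls a [domain_calls()] table
#' @return list with `family`, `sequence_id`, `start`, `end` vectors and a
#'   `vectors` (n_calls x D) matrix, class `domain_embeddings`
#' @export
domain_embeddings <- function(store, calls) {
  missing <- setdiff(unique(calls$sequence_id), names(store))
  if (length(missing)) {
    famsim_stop("missing_key", sprintf(
      "calls reference sequences absent from the embedding store: %s",
      paste(missing, collapse = ", ")))
  }
  vecs <- t(vapply(seq_len(nrow(calls)), function(i) {
    domain_embedding(store[[calls$sequence_id[i]]],
                     calls$start[i], calls$end[i])
  }, numeric(attr(store, "embedding_dim"))))
  structure(list(family = calls$family, sequence_id = calls$sequence_id,
                 start = calls$start, end = calls$end, vectors = vecs),
            class = "domain_embeddings")
}

#' @keywords internal
new_family_embeddings <- function(family, vectors, n_instances) {
  stopifnot(length(family) == nrow(vectors),
            length(family) == length(n_instances), all(n_instances >= 1L))
  rownames(vectors) <- family
  structure(list(family = family, vectors = vectors,
                 n_instances = as.integer(n_instances)),
            class = "family_embeddings")
}

#' Family embeddings: unweighted mean over all instances of each family
#'
#' Families with zero calls are simply absent from the result (the "missing
#' families"); downstream matrices are indexed by the covered set only.
#'
#' @param dom a `domain_embeddings` object
#' @return a `family_embeddings` object (families sorted lexicographically)
#' @export
family_embeddings <- function(dom) {
  fams <- sort(unique(dom$family))
  if (!length(fams)) {
    famsim_stop("no_instances", "no domain embeddings to aggregate")
  }
  vecs <- matrix(0, length(fams), ncol(dom$vectors))
  n <- integer(length(fams))
  for (i in seq_along(fams)) {
    rows <- dom$vectors[dom$family == fams[i], , drop = FALSE]
    vecs[i, ] <- colMeans(rows)
    n[i] <- nrow(rows)
  }
  new_family_embeddings(fams, vecs, n)
}

#' @export
print.family_embeddings <- function(x, ...) {
  cat(sprintf("<family_embeddings: %d families, D = %d, %d instances>\n",
              length(x$family), ncol(x$vectors), sum(x$n_instances)))
  invisible(x)
}

#' Within-sequence residue cosine-similarity heatmap
#'
#' Diagnostic for the smoothness of convolutional embeddings along a
#' sequence: adjacent residues should be more similar than distant ones.
#'
#' @param emb L x D per-residue embedding matrix with no all-zero rows
#' @return symmetric L x L cosine matrix with unit diagonal
#' @export
residue_similarity_heatmap <- function(emb) {
  emb <- as.matrix(emb)
  nrm <- sqrt(rowSums(emb^2))
  if (any(nrm == 0)) {
    famsim_stop("zero_norm", sprintf(
      "residue row(s) with zero norm: %s",
      paste(which(nrm == 0), collapse = ", ")))
  }
  u <- emb / nrm
  s <- tcrossprod(u)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

#' Coverage report: which families obtained an embedding
#'
#' The clan map defines the universe of families; the report counts how many
#' of them are represented in the family embeddings and lists the missing
#' set.
#'
#' @param fe a `family_embeddings` object, or a character vector of covered
#'   family accessions
#' @param cm a `clan_map`
#' @return list with `n_total`, `n_covered`, `pct_covered` (one decimal),
#'   and `missing` (character vector)
#' @export
coverage_report <- function(fe, cm) {
  covered <- if (inherits(fe, "family_embeddings")) fe$family
             else as.character(fe)
  universe <- cm$family
  n_cov <- sum(universe %in% covered)
  pct <- if (length(universe)) round(100 * n_cov / length(universe), 1) else NA_real_
  list(n_total = length(universe), n_covered = n_cov, pct_covered = pct,
       missing = setdiff(universe, covered))
}
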