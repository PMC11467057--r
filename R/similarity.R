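# Family similarity scores
#
# Three stages:
#   1. raw cosine similarity between family embedding vectors;
#   2. per-family z-normalization: each family's distribution of raw
#      similarities to every other family is standardized with its own
#      empirical mean and (population) standard deviation, computed over the
#      off-diagonal entries of its row, which puts "sticky" families (e.g.
#      coiled coils, whose raw similarities are uniformly inflated) on the
#      same scale as everybody else;
#   3. symmetrization: the normalized matrix is asymmetric, so the two
#      directed scores of a pair are combined (max by default: a confident
#      pair needs at least one direction to be confident).
# The diagonal is carried as NA throughout so self-pairs can never be
# consumed by an evaluation.

#' Raw cosine similarity matrix between family embeddings
#'
#' @param fe a `family_embeddings` object
#' @return a `raw_similarity` object: list(family, matrix) with a symmetric
#'   F x F cosine matrix, unit diagonal
#' @export
cosine_matrix <- function(fe) {
  stopifnot(inherits(fe, "family_embeddings"))
  nrm <- sqrt(rowSums(fe$vectors^2))
  if (any(nrm == 0)) {
    famsim_stop("zero_norm", sprintf(
      "zero-norm family embedding(s): %s",
      paste(fe$family[nrm == 0], collapse = ", ")))
  }
  u <- fe$vectors / nrm
  s <- tcrossprod(u)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(fe$family, fe$family)
  structure(list(family = fe$family, matrix = s), class = "raw_similarity")
}

#' Per-family z-normalization of a raw similarity matrix
#'
#' For each family i, `mu_i` and `sigma_i` are the empirical mean and
#' population standard deviation (ddof = 0) of its off-diagonal raw
#' similarities; row i becomes `(sim(i, j) - mu_i) / sigma_i` for j != i.
#' The self-similarity is excluded from the moments (it is identically 1 and
#' would bias the Gaussian approximation) and the diagonal of the result is
#' NA. A constant row (sigma = 0) is set to zero with a warning naming the
#' family.
#'
#' @param raw a `raw_similarity` object with F >= 3 families
#' @return a `normalized_scores` object: list(family, matrix, mu, sigma)
#' @export
normalize_scores <- function(raw) {
  stopifnot(inherits(raw, "raw_similarity"))
  s <- raw$matrix
  f <- nrow(s)
  if (f < 3L) {
    famsim_stop("too_few_families",
                "normalization needs at least 3 families (>= 2 off-diagonal values per row)")
  }
  off <- s
  diag(off) <- NA_real_
  mu <- rowMeans(off, na.rm = TRUE)
  # population sd over the F-1 off-diagonal values of each row
  sigma <- sqrt(rowMeans((off - mu)^2, na.rm = TRUE))
  z <- (off - mu) / sigma
  bad <- which(sigma == 0)
  if (length(bad)) {
    famsim_warn("constant_row", sprintf(
      "constant similarity row(s), normalized to 0: %s",
      paste(raw$family[bad], collapse = ", ")))
    z[bad, ] <- 0
    diag(z) <- NA_real_
  }
  structure(list(family = raw$family, matrix = z, mu = mu, sigma = sigma),
            class = "normalized_scores")
}

#' Symmetrize directed normalized scores into the final pair score
#'
#' @param normed a `normalized_scores` object
#' @param method "max" (default; a pair is confident if at least one
#'   direction is), "mean" or "min"
#' @return a `final_scores` object: list(matrix, method); symmetric, NA
#'   diagonal
#' @export
aggregate_scores <- function(normed, method = c("max", "mean", "min")) {
  method <- match.arg(method)
  m <- normed$matrix
  tm <- t(m)
  res <- switch(method,
                max = pmax(m, tm),
                mean = (m + tm) / 2,
                min = pmin(m, tm))
  diag(res) <- NA_real_
  structure(list(family = normed$family, matrix = res, method = method),
            class = "final_scores")
}

#' @export
print.final_scores <- function(x, ...) {
  cat(sprintf("<final_scores: %d families, method = %s>\n",
              nrow(x$matrix), x$method))
  invisible(x)
}

#' Extract unordered pair scores from a symmetric score matrix
#'
#' @param scores a `final_scores` object (or any list with a symmetric
#'   `matrix` element with dimnames)
#' @return data.frame fam_i, fam_j (i < j lexicographically), score
#' @export
pair_scores <- function(scores) {
  m <- scores$matrix
  fams <- sort(rownames(m))
  m <- m[fams, fams, drop = FALSE]
  ut <- upper.tri(m)
  idx <- which(ut, arr.ind = TRUE)
  data.frame(fam_i = fams[idx[, 1L]], fam_j = fams[idx[, 2L]],
             score = m[ut], stringsAsFactors = FALSE)
}
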