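# Embedding / probability stores
#
# An EmbeddingStore maps sequence_id -> L x D per-residue embedding matrix;
# a ProbabilityStore maps sequence_id -> L x C per-residue class-probability
# matrix together with the class_index -> family accession table. Both are
# plain named lists with attributes, persisted in the keyed binary container.

#' Construct an embedding store
#'
#' @param matrices named list of L x D numeric matrices, one per sequence id
#' @return an `embedding_store` object with attribute `embedding_dim`
#' @export
embedding_store <- function(matrices) {
  if (length(matrices) > 0) {
    if (is.null(names(matrices)) || any(names(matrices) == "")) {
      famsim_stop("unnamed_keys", "all sequences must have a non-empty id")
    }
    dims <- vapply(matrices, ncol, integer(1))
    if (length(unique(dims)) > 1L) {
      famsim_stop("dim_mismatch", sprintf(
        "embedding dimension differs across sequences: %s",
        paste(unique(dims), collapse = ", ")))
    }
    rows <- vapply(matrices, nrow, integer(1))
    if (any(rows < 1L)) {
      famsim_stop("empty_sequence", "every sequence must have L >= 1 residues")
    }
    for (k in names(matrices)) {
      if (anyNA(matrices[[k]]) || any(!is.finite(matrices[[k]]))) {
        famsim_stop("nonfinite_values",
                    sprintf("sequence '%s' has NaN/Inf embedding values", k))
      }
    }
    dim_d <- dims[[1L]]
  } else {
    dim_d <- NA_integer_
  }
  structure(matrices, embedding_dim = dim_d, class = "embedding_store")
}

#' @export
print.embedding_store <- function(x, ...) {
  cat(sprintf("<embedding_store: %d sequences, D = %s>\n",
              length(x), attr(x, "embedding_dim")))
  invisible(x)
}

#' Write an embedding store to a keyed binary container
#'
#' @param store an `embedding_store`
#' @param path output file
#' @export
write_embedding_store <- function(store, path) {
  stopifnot(inherits(store, "embedding_store"))
  write_container(unclass(store), path,
                  meta = list(kind = "embeddings",
                              embedding_dim = attr(store, "embedding_dim")))
}

#' Read an embedding store from a keyed binary container
#'
#' @param path container file
#' @param keys optional sequence ids for a partial read
#' @return an `embedding_store`
#' @export
read_embedding_store <- function(path, keys = NULL) {
  dat <- read_container(path, keys)
  embedding_store(dat$matrices)
}

#' Construct a probability store
#'
#' @param matrices named list of L x C matrices of per-residue class
#'   probabilities, one per sequence id
#' @param classes character vector of C unique family accessions giving the
#'   column order of every matrix
#' @return a `probability_store`
#' @export
probability_store <- function(matrices, classes) {
  classes <- as.character(classes)
  if (anyDuplicated(classes)) {
    famsim_stop("duplicate_accession", "class accessions must be unique")
  }
  for (k in names(matrices)) {
    m <- matrices[[k]]
    if (ncol(m) != length(classes)) {
      famsim_stop("dim_mismatch", sprintf(
        "sequence '%s' has %d classes, class table has %d",
        k, ncol(m), length(classes)))
    }
    if (anyNA(m) || any(m < 0) || any(m > 1)) {
      famsim_stop("probability_range",
                  sprintf("sequence '%s' has probabilities outside [0, 1]", k))
    }
  }
  structure(matrices, classes = classes, class = "probability_store")
}

#' @export
print.probability_store <- function(x, ...) {
  cat(sprintf("<probability_store: %d sequences, %d classes>\n",
              length(x), length(attr(x, "classes"))))
  invisible(x)
}

#' Write a probability store
#' @param store a `probability_store`
#' @param path output file
#' @export
write_probability_store <- function(store, path) {
  stopifnot(inherits(store, "probability_store"))
  write_container(unclass(store), path,
                  meta = list(kind = "probabilities",
                              classes = attr(store, "classes")))
}

#' Read a probability store
#' @param path container file
#' @param keys optional sequence ids for a partial read
#' @export
read_probability_store <- function(path, keys = NULL) {
  dat <- read_container(path, keys)
  probability_store(dat$matrices, classes = dat$meta$classes)
}

#' Write family embeddings to a keyed binary container
#'
#' One D-vector dataset per family accession; the instance counts travel in
#' the header metadata.
#' @param fe a `family_embeddings` object (see [family_embeddings()])
#' @param path output file
#' @export
write_family_embeddings <- function(fe, path) {
  stopifnot(inherits(fe, "family_embeddings"))
  mats <- lapply(seq_len(nrow(fe$vectors)), function(i) {
    matrix(fe$vectors[i, ], nrow = 1L)
  })
  names(mats) <- fe$family
  write_container(mats, path,
                  meta = list(kind = "family_embeddings",
                              family = fe$family,
                              n_instances = fe$n_instances))
}

#' Read family embeddings from a keyed binary container
#' @param path container file
#' @export
read_family_embeddings <- function(path) {
  dat <- read_container(path)
  fams <- as.character(dat$meta$family)
  vec <- do.call(rbind, dat$matrices[fams])
  rownames(vec) <- fams
  new_family_embeddings(fams, vec, as.integer(dat$meta$n_instances))
}
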