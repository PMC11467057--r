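# Keyed binary array container
#
# A single file holding one float32 matrix per key (sequence id or family
# accession) plus a JSON metadata block, supporting partial reads by key.
# Layout:
#   bytes 1-8   : magic "FAMSIM01"
#   bytes 9-16  : little-endian uint64 byte length of the JSON header
#   header      : UTF-8 JSON {version, meta, entries: {key: [offset,nrow,ncol]}}
#   payload     : column-major float32 matrices, offsets relative to payload
#                 start
# The container deliberately mirrors an HDF5 group of 2-D datasets with a
# group-level attribute, without requiring an HDF5 binding at run time.

CONTAINER_MAGIC <- "FAMSIM01"

#' Write a keyed matrix container
#'
#' @param matrices named list of numeric matrices (all with the same number
#'   of columns when `check_dim` is TRUE)
#' @param path output file
#' @param meta named list of scalar/vector metadata stored in the header
#'   (e.g. `embedding_dim`, a class table)
#' @param check_dim require all matrices to share their column count
#' @return `path`, invisibly
#' @keywords internal
write_container <- function(matrices, path, meta = list(), check_dim = TRUE) {
  if (length(matrices) > 0 && is.null(names(matrices))) {
    famsim_stop("unnamed_keys", "container matrices must be a named list")
  }
  if (anyDuplicated(names(matrices))) {
    famsim_stop("duplicate_key", "duplicate keys in container")
  }
  dims <- vapply(matrices, function(m) c(nrow(m), ncol(m)), integer(2))
  if (check_dim && length(matrices) > 1 && length(unique(dims[2L, ])) != 1L) {
    famsim_stop("dim_mismatch", sprintf(
      "matrices disagree on column dimension: %s",
      paste(unique(dims[2L, ]), collapse = ", ")))
  }
  for (k in names(matrices)) {
    if (anyNA(matrices[[k]]) || any(!is.finite(matrices[[k]]))) {
      famsim_stop("nonfinite_values",
                  sprintf("matrix '%s' contains NaN/Inf/NA values", k))
    }
  }
  sizes <- if (length(matrices)) 4L * dims[1L, ] * dims[2L, ] else integer(0)
  offsets <- if (length(sizes)) cumsum(c(0, sizes[-length(sizes)])) else integer(0)
  entries <- list()
  for (i in seq_along(matrices)) {
    entries[[names(matrices)[i]]] <- c(offsets[i], dims[1L, i], dims[2L, i])
  }
  header <- jsonlite::toJSON(
    list(version = 1L, meta = meta, entries = entries),
    auto_unbox = TRUE, digits = NA)
  header_raw <- charToRaw(as.character(header))

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(CONTAINER_MAGIC), con)
  len <- length(header_raw)
  # uint64 little-endian, written as two uint32 words (R has no 64-bit int IO)
  writeBin(as.integer(c(len %% 2^31, 0L)), con, size = 4L, endian = "little")
  writeBin(header_raw, con)
  for (m in matrices) {
    writeBin(as.numeric(m), con, size = 4L, endian = "little")
  }
  invisible(path)
}

# read the header; returns list(version, meta, entries, payload_start)
read_container_header <- function(path) {
  check_file_exists(path)
  con <- file(path, open = "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = 8L))
  if (!identical(magic, CONTAINER_MAGIC)) {
    famsim_stop("bad_magic",
                sprintf("'%s' is not a famsim container (magic '%s')", path, magic))
  }
  words <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  len <- words[1L]
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = len)),
                               simplifyVector = TRUE)
  header$payload_start <- 16L + len
  header
}

#' Read matrices from a keyed container
#'
#' @param path container file
#' @param keys optional character vector restricting which keys to read
#'   (partial read; other payload bytes are skipped)
#' @return list(matrices = named list, meta = list)
#' @keywords internal
read_container <- function(path, keys = NULL) {
  hdr <- read_container_header(path)
  entries <- hdr$entries
  all_keys <- names(entries)
  if (is.null(keys)) keys <- all_keys
  missing <- setdiff(keys, all_keys)
  if (length(missing)) {
    famsim_stop("missing_key",
                sprintf("keys not in container: %s", paste(missing, collapse = ", ")))
  }
  con <- file(path, open = "rb")
  on.exit(close(con))
  out <- vector("list", length(keys))
  names(out) <- keys
  for (k in keys) {
    e <- as.numeric(entries[[k]])
    seek(con, where = hdr$payload_start + e[1L], origin = "start")
    vals <- readBin(con, "numeric", n = e[2L] * e[3L], size = 4L,
                    endian = "little")
    out[[k]] <- matrix(vals, nrow = e[2L], ncol = e[3L])
  }
  list(matrices = out, meta = hdr$meta)
}
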