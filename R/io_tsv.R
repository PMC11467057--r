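# Tab-separated flat files
#
# All TSVs: tab-separated, header row required, '#' comment lines ignored,
# floats serialized with 6 significant digits. On-disk span coordinates are
# 1-based inclusive (Pfam flat-file convention); in-memory spans are 0-based
# half-open [start, end).

fmt_num <- function(x) sprintf("%.6g", x)

read_tsv_raw <- function(path, required_cols) {
  check_file_exists(path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "",
                          check.names = FALSE, na.strings = character(0))
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    famsim_stop("schema", sprintf("'%s' is missing required column(s): %s",
                                  path, paste(missing, collapse = ", ")))
  }
  df
}

write_tsv_raw <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# ---- clan map ---------------------------------------------------------------

#' Read a family-to-clan membership table
#'
#' Accepts the 2-column (`family`, `clan`) dialect or the 5-column
#' Pfam-A.clans dialect (`family`, `clan`, `clan_id`, `family_id`,
#' `description`); extra columns are ignored. An empty clan field means the
#' family belongs to no clan and is stored as `NA`.
#'
#' @param path TSV file
#' @return a `clan_map`: data.frame with columns `family` (unique) and
#'   `clan` (character, `NA` = no clan)
#' @export
read_clan_map <- function(path) {
  check_file_exists(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(clan_map(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    famsim_stop("schema", sprintf(
      "clan map '%s': row %d has %d field(s); need at least family and clan",
      path, which(nf < 2L)[1L], min(nf)))
  }
  fam <- vapply(parts, `[[`, character(1), 1L)
  cln <- vapply(parts, `[[`, character(1), 2L)
  # tolerate a header row in either dialect
  if (fam[1L] %in% c("family", "family_accession", "pfamA_acc")) {
    fam <- fam[-1L]; cln <- cln[-1L]
  }
  clan_map(fam, cln)
}

#' Construct a clan map
#'
#' @param family character vector of unique family accessions
#' @param clan character vector of clan accessions; `""` or `NA` = no clan
#' @export
clan_map <- function(family, clan) {
  family <- as.character(family)
  clan <- as.character(clan)
  if (anyDuplicated(family)) {
    famsim_stop("duplicate_accession", sprintf(
      "duplicate family accession(s): %s",
      paste(unique(family[duplicated(family)]), collapse = ", ")))
  }
  clan[!is.na(clan) & !nzchar(clan)] <- NA_character_
  structure(data.frame(family = family, clan = clan,
                       stringsAsFactors = FALSE),
            class = c("clan_map", "data.frame"))
}

#' Write a clan map as a 2-column TSV
#' @param cm a `clan_map`
#' @param path output file
#' @export
write_clan_map <- function(cm, path) {
  out <- data.frame(family = cm$family,
                    clan = ifelse(is.na(cm$clan), "", cm$clan))
  write_tsv_raw(out, path)
}

#' Look up clans for a set of families
#' @param cm a `clan_map`
#' @param families character vector
#' @return character vector of clans (`NA` = no clan), erroring on families
#'   absent from the map
#' @export
clan_of <- function(cm, families) {
  idx <- match(families, cm$family)
  if (anyNA(idx)) {
    famsim_stop("unknown_family", sprintf(
      "families absent from clan map: %s",
      paste(families[is.na(idx)], collapse = ", ")))
  }
  cm$clan[idx]
}

# ---- domain calls -----------------------------------------------------------

#' Construct a domain-call table
#'
#' @param sequence_id,family character vectors
#' @param start,end integer 0-based half-open span bounds
#' @param mean_probability mean class probability over the span
#' @return a `domain_calls` data.frame
#' @export
domain_calls <- function(sequence_id = character(0), family = character(0),
                         start = integer(0), end = integer(0),
                         mean_probability = numeric(0)) {
  if (any(end <= start)) {
    famsim_stop("invalid_span", "domain calls need end > start (0-based half-open)")
  }
  structure(data.frame(sequence_id = as.character(sequence_id),
                       family = as.character(family),
                       start = as.integer(start), end = as.integer(end),
                       mean_probability = as.numeric(mean_probability),
                       stringsAsFactors = FALSE),
            class = c("domain_calls", "data.frame"))
}

#' Write domain calls (1-based inclusive coordinates on disk)
#' @param calls a `domain_calls` table
#' @param path output file
#' @export
write_domain_calls <- function(calls, path) {
  out <- data.frame(sequence_id = calls$sequence_id, family = calls$family,
                    start = calls$start + 1L, end = calls$end,
                    mean_probability = calls$mean_probability)
  write_tsv_raw(out, path)
}

#' Read domain calls (converting to 0-based half-open)
#' @param path TSV file
#' @export
read_domain_calls <- function(path) {
  df <- read_tsv_raw(path, c("sequence_id", "family", "start", "end",
                             "mean_probability"))
  if (nrow(df) && any(df$start > df$end)) {
    famsim_stop("invalid_span", sprintf("'%s': start > end on disk", path))
  }
  domain_calls(df$sequence_id, df$family, df$start - 1L, df$end,
               df$mean_probability)
}

# ---- reference domains ------------------------------------------------------

#' Read a reference domain table (SEED/FULL alignments)
#'
#' Columns: `sequence_id`, `family`, `start`, `end` (1-based inclusive on
#' disk), `source` in {SEED, FULL}.
#' @param path TSV file
#' @return data.frame with 0-based half-open `start`/`end`
#' @export
read_reference_domains <- function(path) {
  df <- read_tsv_raw(path, c("sequence_id", "family", "start", "end", "source"))
  bad <- !df$source %in% c("SEED", "FULL")
  if (any(bad)) {
    famsim_stop("schema", sprintf("'%s': source must be SEED or FULL (row %d)",
                                  path, which(bad)[1L]))
  }
  if (nrow(df) && any(df$start > df$end)) {
    famsim_stop("invalid_span", sprintf("'%s': start > end", path))
  }
  df$start <- as.integer(df$start) - 1L
  df$end <- as.integer(df$end)
  df
}

#' Write a reference domain table
#' @param ref data.frame with 0-based half-open spans and a `source` column
#' @param path output file
#' @export
write_reference_domains <- function(ref, path) {
  out <- ref
  out$start <- out$start + 1L
  write_tsv_raw(out[, c("sequence_id", "family", "start", "end", "source")],
                path)
}

# ---- TM-score table ---------------------------------------------------------

#' Construct a TM-score table
#' @param family_i,family_j character vectors (one row per unordered pair)
#' @param tm_score numeric in \[0, 1\]
#' @export
tm_score_table <- function(family_i, family_j, tm_score) {
  tm_score <- as.numeric(tm_score)
  if (any(tm_score < 0 | tm_score > 1)) {
    famsim_stop("tm_range", "tm_score outside [0, 1]")
  }
  a <- pmin(as.character(family_i), as.character(family_j))
  b <- pmax(as.character(family_i), as.character(family_j))
  if (anyDuplicated(paste(a, b))) {
    famsim_stop("duplicate_pair", "more than one row for an unordered family pair")
  }
  structure(data.frame(family_i = a, family_j = b, tm_score = tm_score,
                       stringsAsFactors = FALSE),
            class = c("tm_score_table", "data.frame"))
}

#' Read a TM-score table
#' @param path TSV with columns family_i, family_j, tm_score
#' @export
read_tm_score_table <- function(path) {
  df <- read_tsv_raw(path, c("family_i", "family_j", "tm_score"))
  tm_score_table(df$family_i, df$family_j, df$tm_score)
}

#' Write a TM-score table
#' @param tm a `tm_score_table`
#' @param path output file
#' @export
write_tm_score_table <- function(tm, path) {
  write_tsv_raw(as.data.frame(tm), path)
}

# ---- score matrices (long format) ------------------------------------------

#' Write score matrices as a long-format TSV
#'
#' One row per unordered pair (i < j lexicographically) with columns
#' `fam_i`, `fam_j`, `raw`, `normed_ij`, `normed_ji`, `final`.
#' @param raw a `raw_similarity` matrix object
#' @param normed a `normalized_scores` object
#' @param final a `final_scores` object
#' @param path output file
#' @export
write_score_table <- function(raw, normed, final, path) {
  fams <- sort(rownames(raw$matrix))
  idx <- utils::combn(fams, 2L)
  out <- data.frame(
    fam_i = idx[1L, ], fam_j = idx[2L, ],
    raw = raw$matrix[cbind(idx[1L, ], idx[2L, ])],
    normed_ij = normed$matrix[cbind(idx[1L, ], idx[2L, ])],
    normed_ji = normed$matrix[cbind(idx[2L, ], idx[1L, ])],
    final = final$matrix[cbind(idx[1L, ], idx[2L, ])])
  write_tsv_raw(out, path)
}

#' Read a long-format score table
#' @param path TSV file
#' @return list with `pairs` (the long table) and `final` (a `final_scores`
#'   symmetric matrix object rebuilt from the `final` column)
#' @export
read_score_table <- function(path) {
  df <- read_tsv_raw(path, c("fam_i", "fam_j", "raw", "normed_ij",
                             "normed_ji", "final"))
  fams <- sort(unique(c(df$fam_i, df$fam_j)))
  m <- matrix(NA_real_, length(fams), length(fams),
              dimnames = list(fams, fams))
  m[cbind(df$fam_i, df$fam_j)] <- df$final
  m[cbind(df$fam_j, df$fam_i)] <- df$final
  list(pairs = df,
       final = structure(list(matrix = m, method = "max"),
                         class = "final_scores"))
}

# ---- sensitivity curves -----------------------------------------------------

#' Write a sensitivity curve as TSV
#' @param curve a `sensitivity_curve`
#' @param path output file
#' @export
write_sensitivity_curve <- function(curve, path) {
  write_tsv_raw(as.data.frame(unclass(curve)[c("rank", "score", "fp", "tp",
                                               "tie_block")]), path)
}

#' Read a sensitivity curve from TSV
#' @param path TSV file
#' @export
read_sensitivity_curve <- function(path) {
  df <- read_tsv_raw(path, c("rank", "score", "fp", "tp", "tie_block"))
  structure(list(rank = as.integer(df$rank), score = df$score,
                 fp = as.integer(df$fp), tp = as.integer(df$tp),
                 tie_block = as.integer(df$tie_block)),
            class = "sensitivity_curve")
}
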