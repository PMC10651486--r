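#' Load a CRISPR repeat reference database
#'
#' Reads a FASTA file of CRISPR direct-repeat sequences with subtype labels
#' encoded in the headers and returns a de-duplicated repeat database. The
#' expected header dialect is `id|subtype` (for example `rep0001|I-F`);
#' records whose header does not yield a subtype are labelled `"unknown"`.
#'
#' The reference databases used for genome-scale SRU surveys hold tens of
#' thousands of non-redundant repeats spanning all CRISPR-Cas subtypes;
#' a small synthetic fixture database with the same dialect ships with the
#' package (`system.file("extdata", "repeats_synthetic.fa", package =
#' "srutools")`).
#'
#' @param path Path to a FASTA file.
#' @param header_sep Single character separating id from subtype in headers.
#' @param subtype_pattern Optional regular expression with one capture group
#'   applied to the full header to extract the subtype, overriding
#'   `header_sep`.
#' @param dedup Collapse exact duplicate sequences (keeping the first
#'   occurrence)? Default `TRUE`, matching a 100%-identity, 100%-coverage
#'   de-duplication of the source database.
#'
#' @return A tibble of class `repeat_db` with columns `id`, `sequence`,
#'   `subtype` and an attribute `source` recording the file path.
#' @examples
#' db <- load_repeat_db(system.file("extdata", "repeats_synthetic.fa",
#'                                  package = "srutools"))
#' dplyr::count(db, subtype)
#' @export
load_repeat_db <- function(path, header_sep = "|", subtype_pattern = NULL,
                           dedup = TRUE) {
  if (!file.exists(path)) abort(sprintf("repeat database not found: %s", path))
  # read as raw strings first: the DNA reader silently drops invalid
  # letters, and we want to reject them with the record name instead
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) abort(sprintf("no records in repeat database %s", path))
  headers <- names(seqs)
  if (is.null(subtype_pattern)) {
    parts <- strsplit(headers, header_sep, fixed = TRUE)
    ids <- map_chr(parts, 1)
    subtypes <- map_chr(parts, function(p) if (length(p) >= 2) p[[2]] else "unknown")
  } else {
    ids <- sub("\\s.*$", "", headers)
    m <- regmatches(headers, regexec(subtype_pattern, headers))
    subtypes <- map_chr(m, function(g) if (length(g) >= 2) g[[2]] else "unknown")
  }
  subtypes[!nzchar(subtypes)] <- "unknown"
  sequences <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    abort(sprintf("non-DNA characters in record(s): %s",
                  paste(ids[bad], collapse = ", ")))
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate record id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  db <- tibble(id = ids, sequence = unname(sequences), subtype = subtypes)
  if (dedup) db <- deduplicate_repeats(db)
  attr(db, "source") <- path
  class(db) <- c("repeat_db", class(db))
  db
}

#' Collapse exact duplicate repeat sequences
#'
#' Removes records whose sequence is an exact (forward-strand) string
#' duplicate of an earlier record, preserving order otherwise. Reverse
#' complements are retained as distinct records: the search stage scans
#' both strands, so orientation redundancy in the database is harmless.
#'
#' @param db A `repeat_db` tibble or any data frame with a `sequence` column.
#' @return The input with duplicate-sequence rows dropped.
#' @export
deduplicate_repeats <- function(db) {
  check_columns(db, "sequence", "db")
  out <- db[!duplicated(db$sequence), , drop = FALSE]
  attr(out, "source") <- attr(db, "source")
  if (!inherits(out, "repeat_db")) class(out) <- c("repeat_db", class(out))
  out
}

#' @export
print.repeat_db <- function(x, ...) {
  cat(sprintf("CRISPR repeat database: %d repeats, %d subtypes (source: %s)\n",
              nrow(x), length(unique(x$subtype)),
              attr(x, "source") %||% "in-memory"))
  NextMethod()
}
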