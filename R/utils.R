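# Internal helpers shared across modules: sequence coercion, coordinate
# conversion and the two pairwise-alignment scoring schemes used by the
# SRU filters. Coordinates are 0-based half-open everywhere inside the
# package; conversion to the 1-based inclusive convention of output files
# happens only in the writers (see io.R).

DNA_BASES <- c("A", "C", "G", "T")

# Coerce a genome argument (named character vector, DNAString or
# DNAStringSet) to a named DNAStringSet.
as_dna_set <- function(x, arg = "genome") {
  if (methods::is(x, "DNAStringSet")) {
    if (is.null(names(x))) names(x) <- paste0("contig", seq_along(x))
    return(x)
  }
  if (methods::is(x, "DNAString")) {
    out <- Biostrings::DNAStringSet(x)
    names(out) <- "contig1"
    return(out)
  }
  if (is.character(x)) {
    out <- Biostrings::DNAStringSet(toupper(x))
    if (is.null(names(x))) names(out) <- paste0("contig", seq_along(out))
    else names(out) <- names(x)
    return(out)
  }
  abort(sprintf("`%s` must be a character vector, DNAString or DNAStringSet", arg))
}

# Substitution matrix over A/C/G/T/N. N never counts as a match so that
# hard-masked sequence cannot contribute aligned positions.
nuc_matrix <- function(match, mismatch, n_score = mismatch) {
  letters <- c(DNA_BASES, "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- n_score
  m[, "N"] <- n_score
  m
}

# Scheme used by the repeat search (blastn-short defaults).
search_matrix <- function() nuc_matrix(1, -3)

# Scheme used by the mini-array and flank filters: match +1, mismatch 0,
# gap open/extend 1 (penalty), free end gaps in global mode.
filter_matrix <- function() nuc_matrix(1, 0)

# Percent identity of an alignment: identical positions / alignment
# columns (gap columns included), as in standard tabular search output.
aln_identity <- function(pa) {
  aln_len <- nchar(as.character(Biostrings::pattern(pa)))
  100 * Biostrings::nmatch(pa) / aln_len
}

# Ungapped percent identity between two equal-length strings.
ungapped_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  100 * sum(va == vb) / length(va)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Gap in bp strictly between two 0-based half-open intervals on the same
# contig; overlapping or adjacent intervals have gap 0.
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0L, pmax(start1 - end2, start2 - end1))
}

intervals_overlap <- function(start1, end1, start2, end2) {
  start1 < end2 & start2 < end1
}

# Validate a data frame has the named columns, erroring with the missing one.
check_columns <- function(df, cols, arg = "data") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  arg, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

empty_match_tibble <- function() {
  tibble(
    repeat_id = character(), subtype = character(), contig = character(),
    start = integer(), end = integer(), strand = character(),
    identity = double(), coverage = double(), bit_score = double(),
    e_value = double(), coverage_class = character()
  )
}
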