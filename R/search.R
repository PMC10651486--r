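#' Search parameters for the repeat scan
#'
#' Bundles the scoring and filtering parameters of the short-word local
#' search of database repeats against (masked) genome sequence. Defaults
#' reproduce the production setting of the SRU pipeline: word size 6,
#' short-query nucleotide scoring (match +1, mismatch -3, gap open 5, gap
#' extend 2), matches below 90% identity discarded, per-alignment query
#' coverage >= 90% called full and 50-90% called partial.
#'
#' `lambda` and `k` are the Karlin-Altschul constants of the scoring scheme,
#' used to convert raw Smith-Waterman scores to bit scores
#' (`bits = (lambda * S - ln k) / ln 2`); the defaults are the published
#' constants for the +1/-3 scheme and give bit scores identical to those
#' printed by BLASTN for the same alignments.
#'
#' @param word_size Exact-seed word length (default 6).
#' @param min_identity Minimum percent identity, inclusive (default 90).
#' @param full_coverage Minimum query coverage for a full match (default 90).
#' @param min_partial_coverage Minimum query coverage for a partial match
#'   (default 50).
#' @param match,mismatch,gap_open,gap_extend Alignment scoring (penalties
#'   positive).
#' @param lambda,k,h Karlin-Altschul constants for the scheme.
#' @param max_evalue E-value cap reported to the external backend (default
#'   10; the pipeline applies no E-value filter of its own at this stage).
#' @return A list of class `search_params`.
#' @export
search_params <- function(word_size = 6L, min_identity = 90,
                          full_coverage = 90, min_partial_coverage = 50,
                          match = 1, mismatch = 3, gap_open = 5,
                          gap_extend = 2, lambda = 1.374, k = 0.711,
                          h = 1.31, max_evalue = 10) {
  stopifnot(word_size >= 4, min_partial_coverage > 0,
            min_partial_coverage < full_coverage, full_coverage <= 100)
  structure(
    list(word_size = as.integer(word_size), min_identity = min_identity,
         full_coverage = full_coverage,
         min_partial_coverage = min_partial_coverage,
         match = match, mismatch = mismatch, gap_open = gap_open,
         gap_extend = gap_extend, lambda = lambda, k = k, h = h,
         max_evalue = max_evalue),
    class = "search_params"
  )
}

bits_from_raw <- function(score, params) {
  (params$lambda * score - log(params$k)) / log(2)
}

# BLAST-style E-value with iterative length adjustment (approximate; the
# pipeline carries E-values but never filters on them at this stage).
evalue_from_raw <- function(score, qlen, nlen, params) {
  l <- 0
  for (i in 1:10) {
    l <- log(params$k * pmax(1, qlen - l) * pmax(1, nlen - l)) / params$h
    l <- pmax(0, l)
  }
  params$k * pmax(1, qlen - l) * pmax(1, nlen - l) * exp(-params$lambda * score)
}

#' Classify query coverage of a repeat match
#'
#' @param coverage Percent of the repeat (query) length covered by the
#'   alignment, in `[0, 100]`.
#' @param params A [search_params()] object.
#' @return `"full"` (coverage >= 90 by default), `"partial"` (in
#'   `[50, 90)`) or `"reject"` (< 50).
#' @examples
#' classify_coverage(c(95, 70, 49))
#' @export
classify_coverage <- function(coverage, params = search_params()) {
  stopifnot(all(coverage >= 0 & coverage <= 100))
  dplyr::case_when(
    coverage >= params$full_coverage ~ "full",
    coverage >= params$min_partial_coverage ~ "partial",
    TRUE ~ "reject"
  )
}

#' Search database repeats against masked sequence
#'
#' Finds local alignments of every database repeat on both strands of the
#' masked input sequence, keeps matches with identity >= 90% and query
#' coverage >= 50%, and labels each match full or partial. Matches never
#' extend into masked (`N`) positions.
#'
#' Two backends are available: `"internal"`, a seed-and-extend
#' Smith-Waterman search (exact word-size-6 seeds, banded candidate
#' windows, full local DP on survivors) whose bit scores use the
#' Karlin-Altschul constants in `params`; and `"blast"`, which shells out
#' to the BLAST+ `blastn` binary in short-query mode (`-task blastn-short
#' -word_size 6`). The two backends produce identical bit scores for the
#' same alignments, so the downstream 41.1-bit threshold applies to both.
#'
#' @param masked A `masked_seqs` object from [mask_sequence()], or a raw
#'   genome (no masking) as accepted by [mask_sequence()].
#' @param db A `repeat_db` tibble from [load_repeat_db()].
#' @param params A [search_params()] object.
#' @param backend `"internal"` or `"blast"`.
#' @return A tibble with one row per match: `repeat_id`, `subtype`,
#'   `contig`, `start`, `end` (0-based half-open), `strand`, `identity`,
#'   `coverage`, `bit_score`, `e_value`, `coverage_class`, sorted by
#'   (contig, start).
#' @export
search_repeats <- function(masked, db, params = search_params(),
                           backend = c("internal", "blast")) {
  backend <- match.arg(backend)
  if (!inherits(masked, "masked_seqs")) masked <- mask_sequence(masked, NULL)
  check_columns(db, c("id", "sequence", "subtype"), "db")
  if (nrow(db) == 0) abort("repeat database is empty")
  if (sum(Biostrings::width(masked$masked)) == 0) abort("masked sequence is empty")

  matches <- switch(backend,
    internal = search_internal(masked, db, params),
    blast = search_blast(masked, db, params)
  )
  matches <- drop_masked_matches(matches, masked$intervals)
  arrange(matches, .data$contig, .data$start, .data$end, .data$repeat_id)
}

drop_masked_matches <- function(matches, mask_intervals) {
  if (nrow(matches) == 0 || nrow(mask_intervals) == 0) return(matches)
  keep <- map_lgl(seq_len(nrow(matches)), function(i) {
    iv <- mask_intervals[mask_intervals$contig == matches$contig[i], , drop = FALSE]
    !any(intervals_overlap(matches$start[i], matches$end[i], iv$start, iv$end))
  })
  matches[keep, , drop = FALSE]
}

#' Resolve overlapping matches by bit score
#'
#' Among matches sharing at least one subject bp (regardless of strand or
#' of which repeat matched), only the match with the highest bit score is
#' kept. Ties are broken by lower start, then lexicographically smaller
#' repeat id.
#'
#' @param matches A match tibble from [search_repeats()].
#' @return The overlap-free subset, sorted by (contig, start).
#' @export
resolve_overlaps <- function(matches) {
  if (nrow(matches) == 0) return(matches)
  check_columns(matches, c("contig", "start", "end", "bit_score", "repeat_id"),
                "matches")
  resolved <- matches |>
    group_by(.data$contig) |>
    dplyr::group_modify(function(grp, key) resolve_overlaps_contig(grp)) |>
    ungroup()
  arrange(resolved, .data$contig, .data$start, .data$end, .data$repeat_id)
}

# Greedy elimination: repeatedly keep the highest-bit-score match and
# discard everything overlapping it.
resolve_overlaps_contig <- function(grp) {
  ord <- if ("repeat_id" %in% names(grp)) {
    order(-grp$bit_score, grp$start, grp$repeat_id)
  } else {
    order(-grp$bit_score, grp$start)
  }
  grp <- grp[ord, , drop = FALSE]
  kept <- logical(nrow(grp))
  for (i in seq_len(nrow(grp))) {
    j <- which(kept)
    if (!any(intervals_overlap(grp$start[i], grp$end[i], grp$start[j], grp$end[j]))) {
      kept[i] <- TRUE
    }
  }
  grp[kept, , drop = FALSE]
}
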