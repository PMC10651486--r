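# Internal seed-and-extend Smith-Waterman backend.
#
# For each contig the subject is encoded once as an integer base vector and
# an ordered word-size k-mer code index. For each repeat and strand, exact
# k-mer seeds are located by binary search; every seed diagonal is scored
# by a cheap ungapped diagonal count, surviving diagonals are merged into
# candidate windows, and full local dynamic programming (Biostrings
# pairwiseAlignment, short-query scoring) runs only on those windows. Like
# any seeded heuristic, matches with no exact word-size seed are missed;
# this mirrors the word-size-6 behaviour of the production search tool.

BASE_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L)

encode_bases <- function(seq_chr) {
  v <- utf8ToInt(seq_chr)
  out <- rep(NA_integer_, length(v))
  out[v == 65L] <- 0L  # A
  out[v == 67L] <- 1L  # C
  out[v == 71L] <- 2L  # G
  out[v == 84L] <- 3L  # T
  out
}

kmer_codes <- function(b, k) {
  n <- length(b)
  if (n < k) return(integer(0))
  codes <- b[1:(n - k + 1)]
  for (j in 1:(k - 1)) {
    codes <- codes * 4L + b[(1 + j):(n - k + 1 + j)]
  }
  codes
}

# Pre-indexed contig: integer bases plus ordered k-mer code index.
index_contig <- function(seq_chr, k) {
  b <- encode_bases(seq_chr)
  codes <- kmer_codes(b, k)
  ok <- which(!is.na(codes))
  ord <- ok[order(codes[ok])]
  list(bases = b, sorted_codes = codes[ord], positions = ord, n = length(b))
}

# Subject positions (1-based) of every exact seed of `qcodes`; returns a
# list of (qpos, spos) integer vectors.
seed_hits <- function(idx, qcodes) {
  valid <- which(!is.na(qcodes))
  if (length(valid) == 0 || length(idx$sorted_codes) == 0) {
    return(list(qpos = integer(0), spos = integer(0)))
  }
  qc <- qcodes[valid]
  hi <- findInterval(qc, idx$sorted_codes)
  lo <- findInterval(qc - 0.5, idx$sorted_codes) + 1L
  nhit <- pmax(0L, hi - lo + 1L)
  hit <- nhit > 0
  if (!any(hit)) return(list(qpos = integer(0), spos = integer(0)))
  qpos <- rep(valid[hit], nhit[hit])
  spos <- unlist(map2(lo[hit], hi[hit], function(a, b) idx$positions[a:b]),
                 use.names = FALSE)
  list(qpos = qpos, spos = spos)
}

# Minimum diagonal match count worth extending: generous relative to the
# weakest reportable hit (>=50% coverage at >=90% identity).
diag_prefilter_min <- function(overlap) pmax(8L, ceiling(0.4 * overlap))

search_internal <- function(masked, db, params) {
  k <- params$word_size
  out <- vector("list", 0L)
  for (ci in seq_along(masked$masked)) {
    contig <- names(masked$masked)[ci]
    seq_chr <- as.character(masked$masked[[ci]])
    idx <- index_contig(seq_chr, k)
    if (length(idx$sorted_codes) == 0) next
    for (ri in seq_len(nrow(db))) {
      for (strand in c("+", "-")) {
        qseq <- if (strand == "+") db$sequence[ri] else revcomp(db$sequence[ri])
        hits <- align_candidates(idx, seq_chr, qseq, params)
        if (nrow(hits) == 0) next
        hits$repeat_id <- db$id[ri]
        hits$subtype <- db$subtype[ri]
        hits$contig <- contig
        hits$strand <- strand
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  if (length(out) == 0) return(empty_match_tibble())
  matches <- bind_rows(out)
  matches$e_value <- evalue_from_raw(matches$raw_score, nchar(db$sequence[match(matches$repeat_id, db$id)]),
                                     Biostrings::width(masked$masked)[match(matches$contig, names(masked$masked))],
                                     params)
  matches <- matches[matches$e_value <= params$max_evalue, , drop = FALSE]
  # The same alignment can surface from overlapping candidate windows, and
  # a window truncated by its slack can yield a clipped sub-alignment of a
  # stronger hit. Cull per repeat/contig/strand: keep the strongest hit of
  # each overlap group, as a tabular search tool reports its HSPs.
  matches <- matches |>
    group_by(.data$repeat_id, .data$contig, .data$strand) |>
    dplyr::group_modify(function(grp, key) resolve_overlaps_contig(grp)) |>
    ungroup()
  matches$coverage_class <- classify_coverage(matches$coverage, params)
  matches[, names(empty_match_tibble())]
}

# Seed, prefilter and align one query (already strand-oriented) against an
# indexed contig. Returns raw hits in 0-based half-open subject coordinates.
align_candidates <- function(idx, seq_chr, qseq, params) {
  empty <- tibble(start = integer(), end = integer(), identity = double(),
                  coverage = double(), bit_score = double(),
                  raw_score = double())
  L <- nchar(qseq)
  qb <- encode_bases(qseq)
  qcodes <- kmer_codes(qb, params$word_size)
  seeds <- seed_hits(idx, qcodes)
  if (length(seeds$qpos) == 0) return(empty)
  n <- idx$n
  diags <- sort(unique(seeds$spos - seeds$qpos))
  keep <- map_lgl(diags, function(d) {
    ws <- max(1L, d + 1L); we <- min(n, d + L)
    qs <- ws - d; qe <- we - d
    matches <- sum(idx$bases[ws:we] == qb[qs:qe], na.rm = TRUE)
    matches >= diag_prefilter_min(we - ws + 1L)
  })
  diags <- diags[keep]
  if (length(diags) == 0) return(empty)

  # Merge nearby diagonals (gapped alignments shift diagonal slightly)
  # into candidate windows with slack for gaps.
  grp <- cumsum(c(1L, diff(diags) > 10L))
  windows <- tibble(
    d_min = tapply(diags, grp, min),
    d_max = tapply(diags, grp, max)
  ) |>
    mutate(ws = pmax(1L, .data$d_min + 1L - 10L),
           we = pmin(n, .data$d_max + L + 10L))

  win_seqs <- Biostrings::DNAStringSet(substring(seq_chr, windows$ws, windows$we))
  pa <- Biostrings::pairwiseAlignment(
    pattern = win_seqs, subject = Biostrings::DNAString(qseq),
    type = "local", substitutionMatrix = search_matrix(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  raw <- Biostrings::score(pa)
  identity <- aln_identity(pa)
  q_span <- IRanges::end(Biostrings::subject(pa)) -
    IRanges::start(Biostrings::subject(pa)) + 1L
  coverage <- 100 * q_span / L
  s_start1 <- windows$ws - 1L + IRanges::start(Biostrings::pattern(pa))
  s_end1 <- windows$ws - 1L + IRanges::end(Biostrings::pattern(pa))

  res <- tibble(
    start = as.integer(s_start1 - 1L), end = as.integer(s_end1),
    identity = identity, coverage = coverage,
    bit_score = round(bits_from_raw(raw, params), 1),
    raw_score = raw
  )
  res[res$identity >= params$min_identity &
        res$coverage >= params$min_partial_coverage & res$raw_score > 0,
      , drop = FALSE]
}
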