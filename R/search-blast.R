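# External backend: BLAST+ blastn in short-query mode. Queries are the
# database repeats, the subject is the masked genome; tabular output is
# parsed back into the package's match tibble.

blast_available <- function() nzchar(Sys.which("blastn"))

search_blast <- function(masked, db, params) {
  if (!blast_available()) {
    abort(paste0("search backend 'blast' requires the `blastn` executable on ",
                 "PATH; none found. Use backend = \"internal\" for the ",
                 "built-in seed-and-extend Smith-Waterman search."))
  }
  tmp <- tempfile("srublast")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  qfa <- file.path(tmp, "query.fa")
  sfa <- file.path(tmp, "subject.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(setNames(db$sequence, db$id)), qfa)
  Biostrings::writeXStringSet(masked$masked, sfa)
  outfmt <- "6 qseqid sseqid pident length qlen qstart qend sstart send evalue bitscore score sstrand"
  res <- system2("blastn",
                 c("-task", "blastn-short", "-word_size", params$word_size,
                   "-reward", params$match, "-penalty", -params$mismatch,
                   "-gapopen", params$gap_open, "-gapextend", params$gap_extend,
                   "-dust", "no", "-evalue", format(params$max_evalue),
                   "-query", qfa, "-subject", sfa, "-outfmt", shQuote(outfmt)),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(res, "status") %||% 0L
  if (status != 0) abort(paste0("blastn failed: ", paste(res, collapse = "\n")))
  if (length(res) == 0) return(empty_match_tibble())
  cols <- c("qseqid", "sseqid", "pident", "length", "qlen", "qstart", "qend",
            "sstart", "send", "evalue", "bitscore", "score", "sstrand")
  tab <- readr::read_tsv(I(paste(res, collapse = "\n")), col_names = cols,
                         show_col_types = FALSE, progress = FALSE)
  minus <- tab$sstrand == "minus"
  matches <- tibble(
    repeat_id = tab$qseqid,
    subtype = db$subtype[match(tab$qseqid, db$id)],
    contig = as.character(tab$sseqid),
    start = as.integer(ifelse(minus, tab$send, tab$sstart)) - 1L,
    end = as.integer(ifelse(minus, tab$sstart, tab$send)),
    strand = ifelse(minus, "-", "+"),
    identity = tab$pident,
    coverage = 100 * (tab$qend - tab$qstart + 1) / tab$qlen,
    bit_score = tab$bitscore,
    e_value = tab$evalue
  )
  matches <- matches[matches$identity >= params$min_identity &
                       matches$coverage >= params$min_partial_coverage,
                     , drop = FALSE]
  matches$coverage_class <- classify_coverage(matches$coverage, params)
  matches
}
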