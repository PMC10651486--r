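#' Scan sequences for solitary repeat units
#'
#' Runs the full SRU pipeline on one or more contigs in a fixed stage
#' order: ORF masking, short-word repeat search on both strands, overlap
#' resolution by bit score, array clustering, mini-array flagging, flank
#' self-similarity filtering, bit-score thresholding and subtype
#' assignment.
#'
#' @param genome A named character vector, `DNAString` or `DNAStringSet`.
#' @param db A `repeat_db` from [load_repeat_db()].
#' @param orfs ORF annotations ([parse_orf_annotations()]) or `NULL` for
#'   no masking.
#' @param mode `"intergenic"` (production: search outside ORFs) or
#'   `"intragenic"` (threshold calibration: search inside ORFs).
#' @param min_orf_confidence Minimum ORF confidence for masking
#'   (default 80).
#' @param search A [search_params()] object.
#' @param params An [sru_params()] object.
#' @param backend Search backend, `"internal"` or `"blast"`.
#' @return An object of class `sru_scan`: list with `matches` (all raw
#'   matches), `resolved` (overlap-free matches), `srus` (candidate table
#'   with stage verdicts; `final_call` marks SRUs), `arrays`, `funnel`
#'   (stage survivor counts), `mode` and the parameter objects. Supports
#'   [tidy()] (final SRUs), [glance()] (funnel) and [autoplot()].
#' @examples
#' db <- load_repeat_db(system.file("extdata", "repeats_synthetic.fa",
#'                                  package = "srutools"))
#' bg <- random_genome(4000, seed = 7)
#' genome <- paste0(substr(bg, 1, 2000), db$sequence[1],
#'                  substr(bg, 2001, 4000))
#' scan <- sru_scan(c(phage1 = genome), db)
#' tidy(scan)
#' @export
sru_scan <- function(genome, db, orfs = NULL,
                     mode = c("intergenic", "intragenic"),
                     min_orf_confidence = 80,
                     search = search_params(), params = sru_params(),
                     backend = c("internal", "blast")) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  masked <- mask_sequence(genome, orfs, min_confidence = min_orf_confidence,
                          mode = mode)
  unmasked_bp <- sum(Biostrings::width(masked$masked)) - masked_bp(masked)
  matches <- empty_match_tibble()
  resolved <- empty_match_tibble()
  if (unmasked_bp == 0) {
    warn("no unmasked sequence to search; returning empty scan")
  } else {
    matches <- search_repeats(masked, db, search, backend)
    resolved <- resolve_overlaps(matches)
  }
  calls <- call_srus(resolved, masked, params)
  structure(
    list(matches = matches, resolved = resolved,
         srus = calls$srus, arrays = calls$arrays, funnel = calls$funnel,
         mode = mode, search = search, params = params, backend = backend),
    class = "sru_scan"
  )
}

#' @export
print.sru_scan <- function(x, ...) {
  cat(sprintf("SRU scan (%s mode, %s backend)\n", x$mode, x$backend))
  f <- x$funnel
  cat(sprintf("  %d match(es) -> %d full, %d partial; %d array member(s), %d mini-array(s)\n",
              f[["matches"]], f[["full"]], f[["partial"]],
              f[["array_members"]], f[["mini_arrays"]]))
  cat(sprintf("  %d flank-rejected, %d below threshold -> %d final SRU(s)\n",
              f[["flank_rejected"]], f[["threshold_rejected"]],
              f[["final_srus"]]))
  invisible(x)
}

#' @describeIn sru_scan Final SRU calls as a tibble (one row per candidate
#'   passing every filter).
#' @param x An `sru_scan` object.
#' @param ... Unused.
#' @export
tidy.sru_scan <- function(x, ...) {
  filter(x$srus, .data$final_call)
}

#' @describeIn sru_scan One-row summary of the pipeline funnel.
#' @export
glance.sru_scan <- function(x, ...) {
  as_tibble(as.list(x$funnel))
}

#' Run the SRU pipeline on files and write its outputs
#'
#' File-level wrapper around [sru_scan()]: reads the genome FASTA, repeat
#' database and optional ORF GFF3, runs the scan and writes
#' `matches.tsv`, `arrays.tsv`, `srus.tsv` and `config.json` (the echoed
#' configuration, for provenance) into `out_dir`. Output coordinates are
#' 1-based inclusive. Per-stage survivor counts are logged via
#' `message()`.
#'
#' @param fasta Path to the input genome FASTA.
#' @param db_path Path to the repeat database FASTA.
#' @param out_dir Output directory (created if needed).
#' @param orf_gff Optional path to an ORF GFF3.
#' @inheritParams sru_scan
#' @return The `sru_scan` object, invisibly.
#' @export
run_sru_pipeline <- function(fasta, db_path, out_dir, orf_gff = NULL,
                             mode = c("intergenic", "intragenic"),
                             min_orf_confidence = 80,
                             search = search_params(), params = sru_params(),
                             backend = c("internal", "blast")) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  db <- load_repeat_db(db_path)
  orfs <- if (!is.null(orf_gff)) parse_orf_annotations(orf_gff) else NULL
  scan <- sru_scan(genome, db, orfs, mode = mode,
                   min_orf_confidence = min_orf_confidence,
                   search = search, params = params, backend = backend)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_interval_tsv(scan$matches, file.path(out_dir, "matches.tsv"))
  write_interval_tsv(scan$arrays, file.path(out_dir, "arrays.tsv"))
  write_interval_tsv(scan$srus, file.path(out_dir, "srus.tsv"))
  cfg <- list(fasta = fasta, db = db_path, orf_gff = orf_gff, mode = mode,
              min_orf_confidence = min_orf_confidence, backend = backend,
              search = unclass(scan$search), params = unclass(scan$params))
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("pipeline funnel: %s",
                  paste(sprintf("%s=%d", names(scan$funnel), scan$funnel),
                        collapse = " ")))
  invisible(scan)
}
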