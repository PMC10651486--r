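# Readers and writers for the tabular outputs and the benchmark dataset
# directory. Internal coordinates are 0-based half-open; every file this
# module writes uses the 1-based inclusive convention of tabular genomics
# reports, and these converters are the only place conversion happens.

to_out_coords <- function(df) {
  if (nrow(df) > 0) df$start <- df$start + 1L
  df
}

from_out_coords <- function(df) {
  if (nrow(df) > 0) df$start <- df$start - 1L
  df
}

#' Write a tibble with genomic intervals as TSV
#'
#' Converts internal 0-based half-open `start`/`end` to 1-based inclusive
#' before writing.
#'
#' @param df Tibble with `start` and `end` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interval_tsv <- function(df, path) {
  readr::write_tsv(to_out_coords(df), path, progress = FALSE)
  invisible(path)
}

#' Read an interval TSV written by [write_interval_tsv()]
#'
#' @param path Input path.
#' @return A tibble with internal 0-based half-open coordinates.
#' @export
read_interval_tsv <- function(path) {
  from_out_coords(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' Read acr intervals from a BED file
#'
#' The BED name column becomes `id` and the BED score column the
#' prediction score. Hit-level `e_value`/`bit_score` are not representable
#' in BED; they are filled with pass-through values (0 and `Inf`-safe 100)
#' so that [filter_acr_hits()] applies only the prediction-score rule to
#' BED input.
#'
#' @param path Path to a BED file.
#' @return An acr tibble (`contig`, `start`, `end`, `score`, `e_value`,
#'   `bit_score`, `id`), 0-based half-open.
#' @export
read_acr_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  score <- gr$score %||% rep(1, length(gr))
  tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = as.numeric(score),
    e_value = 0,
    bit_score = 100,
    id = as.character(gr$name %||% sprintf("acr%04d", seq_along(gr)))
  )
}

write_orf_gff <- function(orfs, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = orfs$contig,
    ranges = IRanges::IRanges(start = orfs$start + 1L, end = orfs$end),
    strand = orfs$strand
  )
  gr$type <- "CDS"
  gr$source <- "srutools"
  gr$phase <- 0L
  gr$conf <- orfs$confidence
  gr$ID <- sprintf("orf%04d", seq_along(gr))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

write_acr_bed <- function(acrs, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = acrs$contig,
    ranges = IRanges::IRanges(start = acrs$start + 1L, end = acrs$end)
  )
  gr$name <- acrs$id
  gr$score <- acrs$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# Write a benchmark dataset directory: genomes.fasta, orfs.gff3, acrs.bed,
# acrs.tsv (full hit columns), truth.tsv, config.json.
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(bench$genomes),
                              file.path(dir, "genomes.fasta"))
  write_orf_gff(bench$orfs, file.path(dir, "orfs.gff3"))
  write_acr_bed(bench$acrs, file.path(dir, "acrs.bed"))
  write_interval_tsv(bench$acrs, file.path(dir, "acrs.tsv"))
  write_interval_tsv(bench$truth, file.path(dir, "truth.tsv"))
  jsonlite::write_json(c(unclass(bench$config), list(seed = bench$seed)),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a benchmark dataset directory
#'
#' @param dir Directory written by [generate_benchmark()].
#' @return A list with `genomes` (named character), `orfs`, `acrs`,
#'   `truth` tibbles (internal coordinates) and `config` (list).
#' @export
read_benchmark <- function(dir) {
  genomes <- Biostrings::readDNAStringSet(file.path(dir, "genomes.fasta"))
  list(
    genomes = setNames(as.character(genomes), names(genomes)),
    orfs = parse_orf_annotations(file.path(dir, "orfs.gff3")),
    acrs = read_interval_tsv(file.path(dir, "acrs.tsv")),
    truth = read_interval_tsv(file.path(dir, "truth.tsv")),
    config = jsonlite::read_json(file.path(dir, "config.json"),
                                 simplifyVector = TRUE)
  )
}
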