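#' Parse ORF annotations from a GFF3 file
#'
#' Reads CDS features and their prediction confidence from a GFF3 file, as
#' produced by a metagenomic gene caller. Coordinates are converted from the
#' 1-based inclusive GFF convention to the package-internal 0-based
#' half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @param confidence_attr Name of the attribute carrying the caller's
#'   confidence percentage (default `"conf"`). Features lacking the
#'   attribute get confidence 100.
#' @return A tibble with columns `contig`, `start`, `end` (0-based
#'   half-open), `strand` and `confidence`, sorted by (contig, start).
#'   Non-CDS features are skipped.
#' @export
parse_orf_annotations <- function(path, confidence_attr = "conf") {
  if (!file.exists(path)) abort(sprintf("GFF file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^#", lines) & nzchar(trimws(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9)) {
    bad_line <- which(body)[which(nfield != 9)[1]]
    abort(sprintf("malformed GFF line %d: expected 9 tab-separated fields, got %d",
                  bad_line, nfield[which(nfield != 9)[1]]))
  }
  if (!any(body)) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), confidence = double()))
  }
  gff <- suppressWarnings(rtracklayer::readGFF(path))
  gff <- as.data.frame(gff)
  gff <- gff[gff$type == "CDS", , drop = FALSE]
  conf <- if (confidence_attr %in% names(gff)) {
    suppressWarnings(as.numeric(as.character(gff[[confidence_attr]])))
  } else {
    rep(NA_real_, nrow(gff))
  }
  conf[is.na(conf)] <- 100
  tibble(
    contig = as.character(gff$seqid),
    start = as.integer(gff$start) - 1L,
    end = as.integer(gff$end),
    strand = ifelse(as.character(gff$strand) %in% c("+", "-"),
                    as.character(gff$strand), "+"),
    confidence = conf
  ) |>
    arrange(.data$contig, .data$start)
}

#' Hard-mask ORFs in a genome
#'
#' Replaces positions covered by high-confidence ORFs with `N` so that the
#' downstream repeat search is confined to intergenic sequence (the
#' production setting), or masks the complement of those ORFs so the search
#' runs on intragenic sequence (used to calibrate the bit-score threshold
#' against likely false positives).
#'
#' ORFs with confidence below `min_confidence` are ignored; overlapping
#' retained ORFs are merged before masking, so masking depends only on
#' positional coverage, not on gene identity.
#'
#' @param genome A named character vector, `DNAString` or `DNAStringSet`.
#' @param orfs A tibble as returned by [parse_orf_annotations()] (may be
#'   empty or `NULL` for no masking).
#' @param min_confidence Minimum ORF confidence (inclusive) for masking;
#'   default 80.
#' @param mode `"intergenic"` (mask ORFs) or `"intragenic"` (mask
#'   everything except ORFs).
#' @return An object of class `masked_seqs`: a list with elements
#'   `original` and `masked` (`DNAStringSet`s of equal lengths), `intervals`
#'   (tibble of merged masked intervals: `contig`, `start`, `end`) and
#'   `mode`.
#' @examples
#' orfs <- tibble::tibble(contig = "c1", start = 10L, end = 20L,
#'                        strand = "+", confidence = 95)
#' mask_sequence(c(c1 = strrep("A", 30)), orfs)$intervals
#' @export
mask_sequence <- function(genome, orfs = NULL, min_confidence = 80,
                          mode = c("intergenic", "intragenic")) {
  mode <- match.arg(mode)
  genome <- as_dna_set(genome)
  if (is.null(orfs)) {
    orfs <- tibble(contig = character(), start = integer(), end = integer(),
                   strand = character(), confidence = double())
  }
  check_columns(orfs, c("contig", "start", "end", "confidence"), "orfs")
  keep <- orfs$confidence >= min_confidence
  orfs <- orfs[keep, , drop = FALSE]

  lens <- setNames(Biostrings::width(genome), names(genome))
  unknown <- setdiff(unique(orfs$contig), names(genome))
  if (length(unknown) > 0) {
    abort(sprintf("ORF contig(s) not in genome: %s", paste(unknown, collapse = ", ")))
  }
  oob <- orfs$start < 0 | orfs$end > lens[orfs$contig] | orfs$start >= orfs$end
  if (any(oob)) {
    abort(sprintf("ORF interval out of bounds on contig %s: [%d, %d)",
                  orfs$contig[which(oob)[1]], orfs$start[which(oob)[1]],
                  orfs$end[which(oob)[1]]))
  }

  masked <- genome
  interval_rows <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    ctg <- names(genome)[i]
    len <- lens[[ctg]]
    o <- orfs[orfs$contig == ctg, , drop = FALSE]
    orf_ir <- IRanges::reduce(IRanges::IRanges(start = o$start + 1L, end = o$end))
    mask_ir <- if (mode == "intergenic") {
      orf_ir
    } else {
      IRanges::gaps(orf_ir, start = 1L, end = len)
    }
    if (length(mask_ir) > 0) {
      masked[[i]] <- Biostrings::replaceAt(
        genome[[i]], mask_ir,
        Biostrings::DNAStringSet(strrep("N", IRanges::width(mask_ir)))
      )
    }
    interval_rows[[i]] <- tibble(
      contig = ctg,
      start = IRanges::start(mask_ir) - 1L,
      end = IRanges::end(mask_ir)
    )
  }
  structure(
    list(
      original = genome,
      masked = masked,
      intervals = bind_rows(interval_rows),
      mode = mode,
      min_confidence = min_confidence
    ),
    class = "masked_seqs"
  )
}

#' @export
print.masked_seqs <- function(x, ...) {
  total <- sum(Biostrings::width(x$original))
  masked_bp <- sum(x$intervals$end - x$intervals$start)
  cat(sprintf("masked_seqs: %d contig(s), %d bp total, %d bp masked (%s mode)\n",
              length(x$original), total, masked_bp, x$mode))
  invisible(x)
}

# Total masked bp (used by tests of the mode-complement property).
masked_bp <- function(x) sum(x$intervals$end - x$intervals$start)
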