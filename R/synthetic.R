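#' Benchmark generator configuration
#'
#' Describes one family of synthetic MGE genomes with planted ground
#' truth. Per genome the default configuration plants one true solitary
#' repeat unit (at 95% identity to its source database repeat), one
#' CRISPR array of three repeats, one mini-array (full plus truncated
#' copy), one intragenic decoy (repeat inside a high-confidence ORF) and
#' one flank decoy (repeat with a degraded ~75%-identity copy in its
#' upstream flank), plus one acr interval at a fixed gap from the true
#' SRU. Planted identities sit a couple of points away from the 90%/70%
#' decision boundaries; boundary-exact behaviour is exercised by dedicated
#' unit tests, not by the benchmark.
#'
#' @param n_genomes Number of genomes (default 50).
#' @param genome_length Genome length in bp (default 50000).
#' @param gc GC fraction of the random background (default 0.5).
#' @param n_sru,n_array,n_mini_array,n_intragenic_decoy,n_flank_decoy
#'   Feature counts per genome.
#' @param n_acr Number of acr intervals per genome (each placed `acr_gap`
#'   bp downstream of a planted SRU; requires `n_sru >= 1` when positive).
#' @param sru_identity Planted identity (%) of true SRUs (default 95).
#' @param array_size Repeat copies per planted array (default 3).
#' @param array_identity Planted identity of array/mini-array/flank-decoy
#'   full copies (default 98).
#' @param decoy_flank_identity Identity (%) of the degraded copy planted
#'   in a flank decoy's upstream flank (default 75; must exceed 70 to
#'   trigger the flank filter).
#' @param spacer_range Length range (bp) of array spacers and mini-array
#'   gaps; the default 25-40 keeps consecutive repeats within the 100-bp
#'   clustering window, mirroring natural repeat-spacer architecture.
#' @param partial_frac_range Length fraction range of the truncated
#'   mini-array copy (default 0.6-0.8 of the full repeat).
#' @param acr_gap Gap (bp) between a planted SRU and its acr interval
#'   (default 500).
#' @param acr_length Length of planted acr intervals (default 300).
#' @param min_separation Minimum distance (bp) between planted features
#'   (default 500).
#' @param orf_margin Bp of ORF sequence flanking an intragenic decoy's
#'   repeat inside its planted ORF (default 150).
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(n_genomes = 50L, genome_length = 50000L,
                             gc = 0.5, n_sru = 1L, n_array = 1L,
                             n_mini_array = 1L, n_intragenic_decoy = 1L,
                             n_flank_decoy = 1L, n_acr = 1L,
                             sru_identity = 95, array_size = 3L,
                             array_identity = 98,
                             decoy_flank_identity = 75,
                             spacer_range = c(25L, 40L),
                             partial_frac_range = c(0.6, 0.8),
                             acr_gap = 500L, acr_length = 300L,
                             min_separation = 500L, orf_margin = 150L) {
  stopifnot(n_genomes >= 1, genome_length > 0, gc > 0, gc < 1,
            sru_identity >= 90, sru_identity <= 100, array_size >= 2,
            decoy_flank_identity > 70, decoy_flank_identity < 90,
            spacer_range[1] <= spacer_range[2], spacer_range[2] <= 100,
            n_acr == 0 || n_sru >= 1)
  structure(
    list(n_genomes = as.integer(n_genomes),
         genome_length = as.integer(genome_length), gc = gc,
         n_sru = as.integer(n_sru), n_array = as.integer(n_array),
         n_mini_array = as.integer(n_mini_array),
         n_intragenic_decoy = as.integer(n_intragenic_decoy),
         n_flank_decoy = as.integer(n_flank_decoy), n_acr = as.integer(n_acr),
         sru_identity = sru_identity, array_size = as.integer(array_size),
         array_identity = array_identity,
         decoy_flank_identity = decoy_flank_identity,
         spacer_range = as.integer(spacer_range),
         partial_frac_range = partial_frac_range,
         acr_gap = as.integer(acr_gap), acr_length = as.integer(acr_length),
         min_separation = as.integer(min_separation),
         orf_margin = as.integer(orf_margin)),
    class = "benchmark_config"
  )
}

#' Generate a random genome sequence
#'
#' I.i.d. bases with the requested GC fraction; reproducible per seed.
#'
#' @param length Genome length in bp.
#' @param gc GC fraction in (0, 1).
#' @param seed Optional integer seed (sets the RNG when supplied).
#' @return A single uppercase DNA string.
#' @export
random_genome <- function(length, gc = 0.5, seed = NULL) {
  stopifnot(length > 0)
  if (gc <= 0 || gc >= 1) abort("gc must be strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, length, replace = TRUE, prob = probs), collapse = "")
}

#' Mutate a sequence to a target ungapped identity
#'
#' Substitutes bases at positions chosen without replacement so that the
#' ungapped identity of the result to the input equals the nearest
#' achievable value to `target_identity` (granularity `100 / nchar(seq)`;
#' the substitution count is rounded half-up). Substitutions only, never
#' indels.
#'
#' @param seq DNA string.
#' @param target_identity Target identity in `[0, 100]`.
#' @param seed Optional integer seed.
#' @param protect_ends Keep this many bases at each end substitution-free
#'   (default 0: all positions eligible). A substitution within a few
#'   bases of a sequence end gets clipped away by local alignment (the
#'   terminal matches beyond it score less than the mismatch penalty),
#'   silently reducing query coverage.
#' @return The mutated string, with attribute `identity` holding the
#'   achieved (exact) identity.
#' @examples
#' out <- mutate_to_identity("ACGTACGTACGTACGTACGT", 90, seed = 1)
#' attr(out, "identity")
#' @export
mutate_to_identity <- function(seq, target_identity, seed = NULL,
                               protect_ends = 0L) {
  if (target_identity < 0 || target_identity > 100) {
    abort("target_identity must be in [0, 100]")
  }
  if (!is.null(seed)) set.seed(seed)
  v <- strsplit(toupper(seq), "")[[1]]
  len <- length(v)
  n_sub <- floor(len * (100 - target_identity) / 100 + 0.5)  # round half-up
  if (n_sub > 0) {
    eligible <- seq_len(len)
    if (protect_ends > 0) {
      eligible <- eligible[eligible > protect_ends & eligible <= len - protect_ends]
    }
    if (length(eligible) < n_sub) {
      abort("target_identity not achievable with the requested end protection")
    }
    pos <- sample(eligible, n_sub)
    v[pos] <- map_chr(v[pos], function(b) sample(setdiff(DNA_BASES, b), 1))
  }
  out <- paste(v, collapse = "")
  attr(out, "identity") <- 100 * (len - n_sub) / len
  out
}

# Degrade a sequence to a target identity with evenly spaced interior
# substitutions (random replacement bases). All planted copies use this:
# even spacing keeps substitutions away from the sequence ends, where a
# local aligner would clip them and silently shrink query coverage, and
# caps every sub-window's identity near the target. For flank-decoy
# copies it additionally leaves no exact word-size seed at 75% identity,
# so the primary search misses the copy and only the flank
# self-similarity filter can see it (the scenario that filter exists
# for).
mutate_evenly <- function(seq, target_identity) {
  v <- strsplit(toupper(seq), "")[[1]]
  len <- length(v)
  n_sub <- floor(len * (100 - target_identity) / 100 + 0.5)
  if (n_sub > 0) {
    pos <- unique(round(seq(1, len, length.out = n_sub + 2)[-c(1, n_sub + 2)]))
    pos <- pos[seq_len(min(n_sub, length(pos)))]
    v[pos] <- map_chr(v[pos], function(b) sample(setdiff(DNA_BASES, b), 1))
  }
  out <- paste(v, collapse = "")
  attr(out, "identity") <- 100 * (len - n_sub) / len
  out
}

# Reserve non-interfering positions for feature footprints: uniform
# rejection sampling with a minimum separation between reserved blocks.
place_blocks <- function(genome_length, footprints, min_separation, max_tries = 2000L) {
  placed <- tibble(start = integer(0), end = integer(0))
  starts <- integer(length(footprints))
  for (i in seq_along(footprints)) {
    fp <- footprints[i]
    lo <- min_separation
    hi <- genome_length - fp - min_separation
    if (hi < lo) abort("benchmark features do not fit in the genome length")
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample(lo:hi, 1)
      if (!any(intervals_overlap(s - min_separation, s + fp + min_separation,
                                 placed$start, placed$end))) {
        ok <- TRUE
        break
      }
    }
    if (!ok) abort("benchmark features do not fit: could not place all blocks")
    placed <- bind_rows(placed, tibble(start = s, end = s + fp))
    starts[i] <- s
  }
  starts
}

write_into <- function(genome, pos0, insert) {
  substr(genome, pos0 + 1, pos0 + nchar(insert)) <- insert
  genome
}

#' Plant benchmark features into a genome
#'
#' Writes the configured feature set into a random genome and records a
#' ground-truth table. Features are separated by at least
#' `min_separation` bp so they cannot interfere with one another's filter
#' stages.
#'
#' @param genome A single DNA string (the random background).
#' @param db A `repeat_db` tibble; each feature draws a distinct repeat.
#' @param config A [benchmark_config()].
#' @param seed Optional integer seed.
#' @param contig Contig name used in the output tables.
#' @return A list: `genome` (modified string), `truth` (tibble:
#'   `feature_id`, `kind`, `contig`, `start`, `end`, `repeat_id`,
#'   `planted_identity`, `expected_final_call`), `orfs` (ORF annotation
#'   tibble) and `acrs` (acr interval tibble with prediction `score`,
#'   `e_value`, `bit_score` ready for [filter_acr_hits()]).
#' @export
plant_features <- function(genome, db, config = benchmark_config(),
                           seed = NULL, contig = "contig1") {
  if (!is.null(seed)) set.seed(seed)
  n_feat <- config$n_sru + config$n_array + config$n_mini_array +
    config$n_intragenic_decoy + config$n_flank_decoy
  if (n_feat > nrow(db)) abort("repeat database too small for the feature count")
  kinds <- rep(c("sru", "array", "mini_array", "intragenic_decoy", "flank_decoy"),
               times = c(config$n_sru, config$n_array, config$n_mini_array,
                         config$n_intragenic_decoy, config$n_flank_decoy))
  if (length(kinds) == 0) {
    return(list(genome = genome,
                truth = tibble(feature_id = character(), kind = character(),
                               contig = character(), start = integer(),
                               end = integer(), repeat_id = character(),
                               planted_identity = double(),
                               expected_final_call = logical()),
                orfs = tibble(contig = character(), start = integer(),
                              end = integer(), strand = character(),
                              confidence = double()),
                acrs = tibble(contig = character(), start = integer(),
                              end = integer(), score = double(),
                              e_value = double(), bit_score = double(),
                              id = character())))
  }
  reps <- db[sample(nrow(db), length(kinds)), , drop = FALSE]
  spacer <- function() sample(config$spacer_range[1]:config$spacer_range[2], 1)

  # Footprint per feature; the acr interval is reserved inside the first
  # SRU's block so its distance to the SRU is fixed by construction.
  rep_len <- nchar(reps$sequence)
  footprints <- integer(length(kinds))
  for (i in seq_along(kinds)) {
    L <- rep_len[i]
    footprints[i] <- switch(kinds[i],
      sru = L + if (config$n_acr > 0 && i == which(kinds == "sru")[1])
        config$acr_gap + config$acr_length else 0L,
      array = config$array_size * L +
        (config$array_size - 1L) * config$spacer_range[2],
      mini_array = L + config$spacer_range[2] + L,
      intragenic_decoy = L + 2L * config$orf_margin,
      flank_decoy = 2L * L + 100L
    )
  }
  starts <- place_blocks(nchar(genome), footprints, config$min_separation)

  truth <- list(); orfs <- list(); acrs <- list()
  for (i in seq_along(kinds)) {
    kind <- kinds[i]
    L <- rep_len[i]
    rep_seq <- reps$sequence[i]
    s <- starts[i]
    fid <- sprintf("%s_%s_%02d", contig, kind, i)
    if (kind == "sru") {
      planted <- mutate_evenly(rep_seq, config$sru_identity)
      genome <- write_into(genome, s, planted)
      truth[[length(truth) + 1]] <- tibble(
        feature_id = fid, kind = kind, contig = contig, start = s,
        end = s + L, repeat_id = reps$id[i],
        planted_identity = attr(planted, "identity"),
        expected_final_call = TRUE)
      if (config$n_acr > 0 && i == which(kinds == "sru")[1]) {
        for (a in seq_len(config$n_acr)) {
          as_ <- s + L + config$acr_gap
          acrs[[length(acrs) + 1]] <- tibble(
            contig = contig, start = as_, end = as_ + config$acr_length,
            score = round(runif(1, 0.6, 0.99), 3), e_value = 1e-5,
            bit_score = 80, id = sprintf("%s_acr%02d", contig, a))
          truth[[length(truth) + 1]] <- tibble(
            feature_id = sprintf("%s_acr%02d", contig, a), kind = "acr",
            contig = contig, start = as_, end = as_ + config$acr_length,
            repeat_id = NA_character_, planted_identity = NA_real_,
            expected_final_call = FALSE)
        }
      }
    } else if (kind == "array") {
      pos <- s
      for (kcopy in seq_len(config$array_size)) {
        copy <- mutate_evenly(rep_seq, config$array_identity)
        genome <- write_into(genome, pos, copy)
        pos <- pos + L + spacer()
      }
      truth[[length(truth) + 1]] <- tibble(
        feature_id = fid, kind = kind, contig = contig, start = s,
        end = pos - 0L, repeat_id = reps$id[i],
        planted_identity = config$array_identity,
        expected_final_call = FALSE)
    } else if (kind == "mini_array") {
      full <- mutate_evenly(rep_seq, config$array_identity)
      part_len <- round(L * runif(1, config$partial_frac_range[1],
                                  config$partial_frac_range[2]))
      # exact prefix of the reference repeat: an unmutated truncation keeps
      # the partial's query coverage at exactly part_len / L, immune to
      # alignment clipping around an interior substitution
      part <- substr(rep_seq, 1, part_len)
      gap <- spacer()
      genome <- write_into(genome, s, full)
      genome <- write_into(genome, s + L + gap, part)
      truth[[length(truth) + 1]] <- tibble(
        feature_id = fid, kind = kind, contig = contig, start = s,
        end = s + L + gap + part_len, repeat_id = reps$id[i],
        planted_identity = config$array_identity,
        expected_final_call = FALSE)
    } else if (kind == "intragenic_decoy") {
      copy <- mutate_evenly(rep_seq, config$array_identity)
      genome <- write_into(genome, s + config$orf_margin, copy)
      orfs[[length(orfs) + 1]] <- tibble(
        contig = contig, start = s, end = s + L + 2L * config$orf_margin,
        strand = "+", confidence = 95)
      truth[[length(truth) + 1]] <- tibble(
        feature_id = fid, kind = kind, contig = contig,
        start = s + config$orf_margin, end = s + config$orf_margin + L,
        repeat_id = reps$id[i], planted_identity = config$array_identity,
        expected_final_call = FALSE)
    } else if (kind == "flank_decoy") {
      copy <- mutate_evenly(rep_seq, config$array_identity)
      degraded <- mutate_evenly(copy, config$decoy_flank_identity)
      gap <- sample(10:max(10, 99 - L), 1)
      # upstream: degraded copy, then gap, then the candidate repeat
      genome <- write_into(genome, s, degraded)
      cand_start <- s + L + gap
      genome <- write_into(genome, cand_start, copy)
      truth[[length(truth) + 1]] <- tibble(
        feature_id = fid, kind = kind, contig = contig, start = cand_start,
        end = cand_start + L, repeat_id = reps$id[i],
        planted_identity = config$array_identity,
        expected_final_call = FALSE)
    }
  }
  empty_orfs <- tibble(contig = character(), start = integer(),
                       end = integer(), strand = character(),
                       confidence = double())
  empty_acrs <- tibble(contig = character(), start = integer(),
                       end = integer(), score = double(), e_value = double(),
                       bit_score = double(), id = character())
  list(genome = genome,
       truth = bind_rows(truth),
       orfs = if (length(orfs)) bind_rows(orfs) else empty_orfs,
       acrs = if (length(acrs)) bind_rows(acrs) else empty_acrs)
}

#' Generate a synthetic benchmark dataset
#'
#' Builds `n_genomes` independent genomes with planted ground truth,
#' optionally writing the dataset to a directory (`genomes.fasta`,
#' `orfs.gff3`, `acrs.bed`, `truth.tsv`, `config.json`). Fully
#' reproducible from the seed.
#'
#' @param config A [benchmark_config()].
#' @param seed Integer seed.
#' @param db A `repeat_db`; defaults to the bundled synthetic fixture
#'   database.
#' @param dir Optional output directory.
#' @return A list of class `sru_benchmark`: `genomes` (named character
#'   vector), `truth`, `orfs`, `acrs` (combined tibbles), `config`,
#'   `seed`.
#' @export
generate_benchmark <- function(config = benchmark_config(), seed = 1L,
                               db = NULL, dir = NULL) {
  if (is.null(db)) {
    db <- load_repeat_db(system.file("extdata", "repeats_synthetic.fa",
                                     package = "srutools"))
  }
  genomes <- character(config$n_genomes)
  names(genomes) <- sprintf("genome%03d", seq_len(config$n_genomes))
  truth <- list(); orfs <- list(); acrs <- list()
  for (g in seq_len(config$n_genomes)) {
    gseed <- (seed * 1000L + g) %% .Machine$integer.max
    bg <- random_genome(config$genome_length, config$gc, seed = gseed)
    planted <- plant_features(bg, db, config, contig = names(genomes)[g])
    genomes[g] <- planted$genome
    truth[[g]] <- planted$truth
    orfs[[g]] <- planted$orfs
    acrs[[g]] <- planted$acrs
  }
  out <- structure(
    list(genomes = genomes, truth = bind_rows(truth), orfs = bind_rows(orfs),
         acrs = bind_rows(acrs), config = config, seed = as.integer(seed)),
    class = "sru_benchmark"
  )
  if (!is.null(dir)) write_benchmark(out, dir)
  out
}

#' @export
print.sru_benchmark <- function(x, ...) {
  cat(sprintf("synthetic SRU benchmark: %d genome(s) x %d bp, %d truth record(s) (seed %d)\n",
              length(x$genomes), x$config$genome_length, nrow(x$truth), x$seed))
  print(dplyr::count(x$truth, .data$kind))
  invisible(x)
}

#' Evaluate pipeline calls against benchmark truth
#'
#' Assigns each truth record the pipeline stage at which it surfaced
#' (final SRU, array, mini-array, flank-rejected, threshold-rejected,
#' partial-only or masked/undetected) and summarises recovery: every
#' planted SRU should be a final call and every planted array, mini-array,
#' intragenic decoy and flank decoy should be rejected at its own stage,
#' making the stage-level confusion matrix diagonal.
#'
#' @param scans An `sru_calls` or `sru_scan` object (contigs are matched
#'   to truth records by name), or a list of such objects.
#' @param truth The benchmark truth tibble.
#' @return A list of class `benchmark_eval`: `truth` with an added
#'   `outcome` column, `confusion` (kind x outcome count tibble),
#'   `sensitivity` (% of planted SRUs recovered as final calls),
#'   `false_calls` (final calls not overlapping a planted SRU) and
#'   `n_final_calls`.
#' @export
evaluate_benchmark <- function(scans, truth) {
  if (inherits(scans, "sru_calls") || inherits(scans, "sru_scan")) {
    scans <- list(scans)
  }
  srus_all <- bind_rows(map(scans, "srus"))
  arrays_all <- bind_rows(map(scans, "arrays"))
  repeats_truth <- filter(truth, .data$kind != "acr")

  outcome <- map_chr(seq_len(nrow(repeats_truth)), function(i) {
    tr <- repeats_truth[i, ]
    ov_sru <- srus_all[srus_all$contig == tr$contig &
                         intervals_overlap(srus_all$start, srus_all$end,
                                           tr$start, tr$end), , drop = FALSE]
    ov_arr <- arrays_all[arrays_all$contig == tr$contig &
                           intervals_overlap(arrays_all$start, arrays_all$end,
                                             tr$start, tr$end), , drop = FALSE]
    if (nrow(ov_sru) > 0 && any(ov_sru$final_call)) return("final_sru")
    if (nrow(ov_arr) > 0 && any(ov_arr$class == "array")) return("array")
    if (nrow(ov_sru) > 0 && any(ov_sru$mini_array_flag)) return("mini_array")
    if (nrow(ov_sru) > 0 && any(!ov_sru$passed_flank_filter)) return("flank_rejected")
    if (nrow(ov_sru) > 0 && any(!ov_sru$passed_threshold)) return("threshold_rejected")
    "masked"
  })
  repeats_truth$outcome <- outcome

  finals <- filter(srus_all, .data$final_call)
  sru_truth <- filter(repeats_truth, .data$kind == "sru")
  false_calls <- sum(map_lgl(seq_len(nrow(finals)), function(i) {
    tr <- sru_truth[sru_truth$contig == finals$contig[i], , drop = FALSE]
    !any(intervals_overlap(finals$start[i], finals$end[i], tr$start, tr$end))
  }))
  sensitivity <- if (nrow(sru_truth) == 0) NA_real_ else
    100 * mean(sru_truth$outcome == "final_sru")
  confusion <- dplyr::count(repeats_truth, .data$kind, .data$outcome)
  structure(
    list(truth = repeats_truth, confusion = confusion,
         sensitivity = sensitivity, false_calls = as.integer(false_calls),
         n_final_calls = nrow(finals)),
    class = "benchmark_eval"
  )
}

#' @export
print.benchmark_eval <- function(x, ...) {
  cat(sprintf("benchmark evaluation: sensitivity %.1f%%, %d false final call(s), %d final call(s)\n",
              x$sensitivity, x$false_calls, x$n_final_calls))
  print(tidyr::pivot_wider(x$confusion, names_from = "outcome",
                           values_from = "n", values_fill = 0L))
  invisible(x)
}

#' @export
glance.benchmark_eval <- function(x, ...) {
  tibble(sensitivity = x$sensitivity, false_calls = x$false_calls,
         n_final_calls = x$n_final_calls)
}
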