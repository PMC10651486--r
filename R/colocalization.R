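#' Filter predicted acr protein hits
#'
#' Applies the acr-gene screening rules: machine-learning prediction score
#' strictly greater than 0.5, alignment E-value at most 0.01 (inclusive),
#' and overlap groups reduced to the highest-bit-score member.
#'
#' @param hits A data frame of tabular protein-search hits with columns
#'   `contig`, `start`, `end` (0-based half-open), `score` (prediction
#'   score in `[0, 1]`), `e_value` and `bit_score` (and optionally `id`).
#' @param min_score Prediction score cut-off, exclusive (default 0.5).
#' @param max_evalue E-value cut-off, inclusive (default 0.01).
#' @return The filtered tibble, sorted by (contig, start).
#' @export
filter_acr_hits <- function(hits, min_score = 0.5, max_evalue = 0.01) {
  check_columns(hits, c("contig", "start", "end", "score", "e_value",
                        "bit_score"), "hits")
  hits <- as_tibble(hits)
  if (!"id" %in% names(hits)) {
    hits$id <- sprintf("acr%04d", seq_len(nrow(hits)))
  }
  kept <- filter(hits, .data$score > min_score, .data$e_value <= max_evalue)
  if (nrow(kept) == 0) return(kept)
  kept <- kept |>
    dplyr::rename(repeat_id = "id") |>
    resolve_overlaps() |>
    dplyr::rename(id = "repeat_id")
  arrange(kept, .data$contig, .data$start)
}

#' Count acr genes within a window of any SRU
#'
#' Counts acr genes whose interval lies within `window` bp (gap distance;
#' an overlapping interval has distance 0) of at least one SRU on the same
#' contig. Each acr gene is counted at most once, however many SRUs it
#' neighbours.
#'
#' @param srus Tibble of SRUs with `contig`, `start`, `end`.
#' @param acrs Tibble of acr intervals with `contig`, `start`, `end`.
#' @param window Proximity window in bp, default 1000.
#' @return Integer count.
#' @export
count_acr_within <- function(srus, acrs, window = 1000L) {
  if (nrow(srus) == 0 || nrow(acrs) == 0) return(0L)
  check_columns(srus, c("contig", "start", "end"), "srus")
  check_columns(acrs, c("contig", "start", "end"), "acrs")
  hit <- map_lgl(seq_len(nrow(acrs)), function(i) {
    s <- srus[srus$contig == acrs$contig[i], , drop = FALSE]
    nrow(s) > 0 && any(interval_gap(s$start, s$end, acrs$start[i], acrs$end[i]) <= window)
  })
  sum(hit)
}

#' Permutation test of SRU-acr co-localization
#'
#' Tests whether acr genes lie within `window` bp of SRUs more often than
#' expected if SRU positions were random. The observed statistic is
#' [count_acr_within()]. In each of `n_perm` replicates every SRU is
#' independently relocated to a uniform random start on its own contig
#' (length and contig preserved; acr positions fixed) and the statistic is
#' recomputed. The one-tailed P value uses add-one smoothing with a strict
#' exceedance rule:
#' \deqn{P = (|\{r : \mathrm{perm}_r > \mathrm{obs}\}| + 1) / (n_{perm} + 1)}
#'
#' @param srus Tibble of SRUs (`contig`, `start`, `end`).
#' @param acrs Tibble of filtered acr intervals ([filter_acr_hits()]).
#' @param contig_lengths Named numeric vector, or tibble with columns
#'   `contig` and `length`, giving the length of every SRU-bearing contig.
#' @param window Proximity window in bp (default 1000).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `sru_permutation`: list with `observed`,
#'   `permuted` (integer vector of length `n_perm`), `p_value`, `n_perm`,
#'   `window` and `seed`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
acr_permutation_test <- function(srus, acrs, contig_lengths, window = 1000L,
                                 n_perm = 1000L, seed = 1L) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (is.data.frame(contig_lengths)) {
    check_columns(contig_lengths, c("contig", "length"), "contig_lengths")
    contig_lengths <- setNames(contig_lengths$length, contig_lengths$contig)
  }
  check_columns(srus, c("contig", "start", "end"), "srus")
  missing_len <- setdiff(unique(srus$contig), names(contig_lengths))
  if (length(missing_len) > 0) {
    abort(sprintf("no length for contig(s): %s", paste(missing_len, collapse = ", ")))
  }
  lens <- unname(contig_lengths[srus$contig])
  widths <- srus$end - srus$start
  if (any(widths > lens)) abort("contig shorter than its SRU")

  observed <- count_acr_within(srus, acrs, window)
  set.seed(seed)
  permuted <- integer(n_perm)
  for (r in seq_len(n_perm)) {
    permuted[r] <- count_acr_within(relocate_srus(srus, lens), acrs, window)
  }
  p <- (sum(permuted > observed) + 1) / (n_perm + 1)
  structure(
    list(observed = observed, permuted = permuted, p_value = p,
         n_perm = as.integer(n_perm), window = as.integer(window),
         seed = as.integer(seed)),
    class = "sru_permutation"
  )
}

# One null replicate: each SRU independently relocated to a uniform
# random start on its own contig; lengths and contigs preserved.
relocate_srus <- function(srus, lens) {
  widths <- srus$end - srus$start
  new_start <- floor(runif(nrow(srus), min = 0, max = lens - widths + 1))
  srus$start <- as.integer(new_start)
  srus$end <- as.integer(new_start + widths)
  srus
}

#' @export
print.sru_permutation <- function(x, ...) {
  cat(sprintf("acr co-localization permutation test (window %d bp)\n", x$window))
  cat(sprintf("  observed: %d acr gene(s) near an SRU\n", x$observed))
  cat(sprintf("  permuted: mean %.2f (n_perm = %d, seed = %d)\n",
              mean(x$permuted), x$n_perm, x$seed))
  cat(sprintf("  one-tailed P = %.4g\n", x$p_value))
  invisible(x)
}

#' @export
tidy.sru_permutation <- function(x, ...) {
  tibble(replicate = seq_len(x$n_perm), count = x$permuted)
}

#' @export
glance.sru_permutation <- function(x, ...) {
  tibble(observed = x$observed, permuted_mean = mean(x$permuted),
         permuted_sd = sd(x$permuted), p_value = x$p_value,
         n_perm = x$n_perm, window = x$window, seed = x$seed)
}

#' Permutation test of SRU-subtype / host-subtype association
#'
#' Measures how often an SRU's assigned subtype matches a cas-operon
#' subtype present in its host (restricted, by construction of the input,
#' to SRUs whose host carries at least one cas operon), and compares the
#' observed match fraction to the distribution obtained by shuffling the
#' SRU subtype labels across hosts (permutation of the label multiset
#' without replacement).
#'
#' @param data A data frame with one row per SRU: column `sru_subtype`
#'   (character) and column `host_subtypes`, either a list column of
#'   character vectors or a comma-separated character column of the host's
#'   cas-operon subtypes.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return An object of class `subtype_association`: list with
#'   `observed_fraction`, `permuted_mean`, `permuted_sd` (sample SD), all
#'   in percent, `permuted` (vector of replicate fractions), `n`,
#'   `n_perm`, `seed`. Supports [tidy()] and [glance()].
#' @export
subtype_association_test <- function(data, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  check_columns(data, c("sru_subtype", "host_subtypes"), "data")
  if (nrow(data) == 0) abort("no SRUs to test")
  labels <- as.character(data$sru_subtype)
  sets <- data$host_subtypes
  if (!is.list(sets)) sets <- strsplit(as.character(sets), "\\s*,\\s*")
  match_frac <- function(lab) 100 * mean(map2_lgl(lab, sets, ~ .x %in% .y))
  observed <- match_frac(labels)
  set.seed(seed)
  permuted <- map_dbl(seq_len(n_perm), function(r) match_frac(sample(labels)))
  structure(
    list(observed_fraction = observed, permuted_mean = mean(permuted),
         permuted_sd = sd(permuted), permuted = permuted,
         n = nrow(data), n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "subtype_association"
  )
}

#' @export
print.subtype_association <- function(x, ...) {
  cat(sprintf("SRU-subtype vs host cas-subtype association (n = %d SRUs)\n", x$n))
  cat(sprintf("  observed match: %.1f%%\n", x$observed_fraction))
  cat(sprintf("  permuted: %.1f%% +/- %.1f%% (n_perm = %d, seed = %d)\n",
              x$permuted_mean, x$permuted_sd, x$n_perm, x$seed))
  invisible(x)
}

#' @export
tidy.subtype_association <- function(x, ...) {
  tibble(replicate = seq_len(x$n_perm), match_fraction = x$permuted)
}

#' @export
glance.subtype_association <- function(x, ...) {
  tibble(observed_fraction = x$observed_fraction,
         permuted_mean = x$permuted_mean, permuted_sd = x$permuted_sd,
         n = x$n, n_perm = x$n_perm, seed = x$seed)
}
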