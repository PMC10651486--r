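#' Calibrate the bit-score threshold from labelled matches
#'
#' Recovers the bit-score cut-off separating candidate matches found in
#' intergenic regions (likely true SRUs) from matches found in intragenic
#' regions (likely false positives), as a depth-1 recursive-partitioning
#' split: the single split point on bit score minimizing the weighted Gini
#' impurity of the two induced partitions. Candidate split points are the
#' midpoints between consecutive distinct sorted scores; ties are broken
#' toward the lowest threshold. This is the exact one-feature special case
#' of a CART decision stump.
#'
#' The shipped default threshold (41.1 bits) is the production calibration
#' of this procedure on a database-scale intergenic/intragenic contrast
#' and is used by [sru_params()] regardless of local re-calibration.
#'
#' @param data A data frame with one row per match.
#' @param bit_score,label Column names (strings) holding the numeric bit
#'   score and the two-level region label.
#' @param positive Label value treated as the intergenic (true-candidate)
#'   class; defaults to `"intergenic"` when present.
#' @return A list of class `threshold_calibration`: `threshold`,
#'   `impurity` (weighted Gini at the split), `baseline_impurity`,
#'   `purity_above` (fraction of the positive class at or above the
#'   threshold) and `n`.
#' @examples
#' d <- tibble::tibble(bit_score = c(30, 35, 40, 50, 55),
#'                     label = c("intragenic", "intragenic", "intragenic",
#'                               "intergenic", "intergenic"))
#' calibrate_threshold(d)$threshold
#' @export
calibrate_threshold <- function(data, bit_score = "bit_score", label = "label",
                                positive = NULL) {
  check_columns(data, c(bit_score, label), "data")
  x <- data[[bit_score]]
  y <- as.character(data[[label]])
  stopifnot(is.numeric(x), !anyNA(x), !anyNA(y))
  lv <- unique(y)
  if (length(lv) < 2) abort("no split: only one label present")
  if (length(lv) > 2) abort("label must have exactly two levels")
  positive <- positive %||% (if ("intergenic" %in% lv) "intergenic" else lv[1])

  gini <- function(p) 2 * p * (1 - p)
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  pos <- as.integer(y[ord] == positive)
  distinct <- which(diff(xs) > 0)
  if (length(distinct) == 0) {
    # All scores identical: no informative split; report the degenerate
    # threshold at the common value with baseline impurity.
    p <- mean(pos)
    return(structure(list(threshold = xs[1], impurity = gini(p),
                          baseline_impurity = gini(p),
                          purity_above = p, n = n),
                     class = "threshold_calibration"))
  }
  cum_pos <- cumsum(pos)
  # Split after position i: below = 1..i, above = (i+1)..n.
  i <- distinct
  p_below <- cum_pos[i] / i
  p_above <- (cum_pos[n] - cum_pos[i]) / (n - i)
  imp <- (i * gini(p_below) + (n - i) * gini(p_above)) / n
  best <- which(imp == min(imp))[1]  # ties -> lowest midpoint
  thr <- (xs[i[best]] + xs[i[best] + 1]) / 2
  structure(
    list(threshold = thr, impurity = imp[best],
         baseline_impurity = gini(mean(pos)),
         purity_above = p_above[best], n = n),
    class = "threshold_calibration"
  )
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("bit-score threshold: %.3f (Gini %.4f vs baseline %.4f; %.1f%% positive above; n = %d)\n",
              x$threshold, x$impurity, x$baseline_impurity,
              100 * x$purity_above, x$n))
  invisible(x)
}

#' @export
glance.threshold_calibration <- function(x, ...) {
  tibble(threshold = x$threshold, impurity = x$impurity,
         baseline_impurity = x$baseline_impurity,
         purity_above = x$purity_above, n = x$n)
}
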