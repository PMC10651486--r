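# ggplot2 visualisations for the main result types.

#' @describeIn acr_permutation_test Histogram of the permuted null counts
#'   with the observed count marked (the usual display of a positional
#'   permutation test).
#' @param object An `sru_permutation` object.
#' @param ... Unused.
#' @export
autoplot.sru_permutation <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, linewidth = 1) +
    ggplot2::labs(
      x = sprintf("acr genes within %d bp of an SRU", object$window),
      y = "permutations",
      title = sprintf("observed = %d, P = %.3g (n_perm = %d)",
                      object$observed, object$p_value, object$n_perm)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn subtype_association_test Histogram of permuted match
#'   fractions with the observed fraction marked.
#' @param object A `subtype_association` object.
#' @param ... Unused.
#' @export
autoplot.subtype_association <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$match_fraction)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_fraction, linewidth = 1) +
    ggplot2::labs(
      x = "SRU subtype matching a host cas subtype (%)",
      y = "permutations",
      title = sprintf("observed = %.1f%%, permuted = %.1f%% ± %.1f%%",
                      object$observed_fraction, object$permuted_mean,
                      object$permuted_sd)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn sru_scan Bar chart of the pipeline funnel (survivors per
#'   stage).
#' @param object An `sru_scan` object.
#' @export
autoplot.sru_scan <- function(object, ...) {
  f <- object$funnel
  stages <- c("matches", "full", "solitary", "final_srus")
  df <- tibble(stage = factor(stages, levels = stages),
               count = as.integer(f[stages]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "matches surviving",
                  title = sprintf("SRU pipeline funnel (%s mode)", object$mode)) +
    ggplot2::theme_minimal()
}
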