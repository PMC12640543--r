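#' Plot the permutation null of an Snn test
#'
#' Histogram of the permuted Snn values with the observed statistic
#' marked. Requires the test to have been run with
#' `keep_permutations = TRUE`.
#'
#' @param object An `snn_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.snn_result <- function(object, ...) {
  if (is.null(object$permuted_values)) {
    abort("re-run snn_permutation_test() with keep_permutations = TRUE to plot the null")
  }
  df <- tibble(snn = object$permuted_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$snn)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$snn, colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "Snn under permuted location labels",
      y = "permutations",
      title = sprintf("Snn = %.3f, p = %.3g", object$snn, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of coding-complete genotype counts per sample and segment
#'
#' @param object A [coinfection_profile()].
#' @param coinfected_only Show only coinfected samples (default TRUE).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coinfection_profile <- function(object, coinfected_only = TRUE, ...) {
  samples <- attr(object, "samples")
  df <- as_tibble(object)
  if (coinfected_only) {
    df <- filter(df, .data$sample_id %in% samples$sample_id[samples$coinfected])
  }
  df$segment <- factor(df$segment, levels = segment_levels())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$segment, y = .data$sample_id,
                                   fill = factor(.data$n_genotypes))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_brewer(palette = "Blues", name = "genotypes") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of pairwise identities with the median marked
#'
#' @param distribution Result of [identity_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_identity_distribution <- function(distribution, ...) {
  med <- attr(distribution, "median")
  ggplot2::ggplot(as_tibble(distribution), ggplot2::aes(x = .data$identity)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = med, colour = "firebrick", linetype = 2) +
    ggplot2::labs(
      x = "pairwise nucleotide identity (%)", y = "sequence pairs",
      title = sprintf("median %.1f%%", med)
    ) +
    ggplot2::theme_minimal()
}
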