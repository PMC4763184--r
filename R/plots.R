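#' Plot the ADA threshold profile
#'
#' Permutation P-value per truncation threshold and direction; the optimal
#' threshold is marked by a vertical line.
#'
#' @param object An `ada_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ada_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$p_permutation,
                                   colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$optimal_threshold, linetype = 2) +
    ggplot2::labs(x = "P-value truncation threshold",
                  y = "permutation P-value of the score",
                  title = sprintf("ADA profile (final P = %.3g)", object$final_p)) +
    ggplot2::theme_minimal()
}

#' Plot backward-elimination return counts
#'
#' Return count per variant, coloured by the interesting / non-interesting
#' partition.
#'
#' @param object A `be_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.be_fit <- function(object, ...) {
  df <- object$counts
  df$variant_id <- factor(df$variant_id, levels = df$variant_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variant_id, y = .data$return_count,
                                   fill = .data$interesting)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "return count",
                  title = sprintf("BE-%s return counts", toupper(object$inner_test))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot an evaluation summary
#'
#' Mean true/false positives per method for the unrestricted stratum.
#'
#' @param summary A [summarize_selections()] tibble.
#' @return A ggplot object.
#' @export
plot_evaluation <- function(summary) {
  df <- summary |>
    dplyr::filter(.data$stratum == "all") |>
    tidyr::pivot_longer(c("tp_mean", "fp_mean"),
                        names_to = "metric", values_to = "mean_count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$mean_count,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "mean count per replicate") +
    ggplot2::theme_minimal()
}
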