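#' Plot methods
#'
#' ggplot2 visualisations of the package's result tables.
#'
#' * `autoplot(<va_csmf>)`: bar chart of cause-specific mortality
#'   fractions.
#' * `autoplot(<va_csmf_comparison>)`: side-by-side bars per group for
#'   the two methods, annotated with the CSMF accuracy.
#' * `autoplot(<va_agreement_report>)`: kappa with 95% CI per stratum.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name va_plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname va_plots
#' @method autoplot va_csmf
#' @export
autoplot.va_csmf <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$group, -.data$fraction),
    y = .data$fraction
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(
      x = NULL, y = "Cause-specific mortality fraction",
      title = paste0("CSMF (", df$method[1], ", ", df$stratum[1], ")"),
      subtitle = paste0("n = ", attr(object, "n"))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname va_plots
#' @method autoplot va_csmf_comparison
#' @export
autoplot.va_csmf_comparison <- function(object, ...) {
  df <- as_tibble(object) %>%
    select("group", "fraction_a", "fraction_b") %>%
    tidyr::pivot_longer(c("fraction_a", "fraction_b"),
                        names_to = "method", values_to = "fraction") %>%
    mutate(method = ifelse(
      .data$method == "fraction_a",
      attr(object, "method_a"), attr(object, "method_b")
    ))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$group, y = .data$fraction, fill = .data$method
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(
      x = NULL, y = "Cause-specific mortality fraction",
      fill = "Method",
      title = paste0("CSMF by method (", attr(object, "stratum"), ")"),
      subtitle = sprintf("CSMF accuracy = %.3f", attr(object, "csmf_accuracy"))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname va_plots
#' @method autoplot va_agreement_report
#' @export
autoplot.va_agreement_report <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$kappa)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$ci_low, ymax = .data$ci_high
    )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = "Cohen's kappa (95% CI)",
      title = "Chance-corrected agreement by stratum"
    ) +
    ggplot2::theme_minimal()
}
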