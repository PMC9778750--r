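#' Box plot of iAs concentration by stratum
#'
#' @param data A concentration tibble.
#' @param by Metadata column to stratify by (default `rice_type`).
#' @return A ggplot object.
#' @export
plot_concentration <- function(data, by = "rice_type") {
  if (!by %in% names(data)) {
    abort(sprintf("Unknown grouping column: %s", by),
          class = "ricerisk_usage_error")
  }
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[by]], y = .data$ias_ng_g)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = by, y = "iAs concentration (ng/g raw rice)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.risk_summary <- function(object, metric = c("risk", "hq"), ...) {
  metric <- match.arg(metric)
  col <- paste0(metric, "_mean")
  df <- object$per_group
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data[[col]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "Age group",
      y = if (metric == "risk") "Mean incremental cancer risk"
          else "Mean fractional hazard quotient"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.concentration_fits <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family, y = .data$aic,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70"),
                               guide = "none") +
    ggplot2::labs(x = "Candidate family", y = "AIC (lower is better)") +
    ggplot2::theme_minimal()
}
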