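#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Letter-value plot of counting errors
#'
#' A boxen-style display: nested boxes for successive letter-value pairs
#' (median, fourths, eighths, ...), with remaining points drawn as
#' outliers. Suited to the heavy-tailed, spiky distributions of counting
#' errors.
#'
#' @param errors Output of [counting_error()] (columns `organ`, `error`),
#'   or any tibble with a grouping column and a value column.
#' @param value,group Column names (strings) of the value and grouping
#'   variable.
#' @return A ggplot object.
#' @export
plot_letter_values <- function(errors, value = "error", group = "organ") {
  df <- as_tibble(errors)
  groups <- unique(df[[group]])
  layers <- purrr::map_dfr(seq_along(groups), function(gi) {
    vals <- df[[value]][df[[group]] == groups[gi]]
    lv <- letter_values(vals)
    k <- nrow(lv)
    tibble(group = groups[gi],
           letter = lv$letter,
           depth_rank = seq_len(k),
           lower = lv$lower, upper = lv$upper,
           width = 0.9 * 0.75^(seq_len(k) - 1))
  })
  outliers <- purrr::map_dfr(seq_along(groups), function(gi) {
    vals <- df[[value]][df[[group]] == groups[gi]]
    tibble(group = groups[gi],
           value = attr(letter_values(vals), "outliers"))
  })
  gx <- as.numeric(factor(layers$group, levels = groups))
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = mutate(layers, gx = gx),
      ggplot2::aes(xmin = .data$gx - .data$width / 2,
                   xmax = .data$gx + .data$width / 2,
                   ymin = .data$lower, ymax = .data$upper,
                   fill = .data$letter),
      color = "grey30", show.legend = FALSE)
  if (nrow(outliers) > 0) {
    p <- p + ggplot2::geom_point(
      data = mutate(outliers,
                    gx = as.numeric(factor(.data$group, levels = groups))),
      ggplot2::aes(x = .data$gx, y = .data$value),
      shape = 1, size = 1)
  }
  p +
    ggplot2::scale_x_continuous(breaks = seq_along(groups),
                                labels = as.character(groups)) +
    ggplot2::scale_fill_brewer(palette = "Blues", direction = -1) +
    ggplot2::labs(x = group, y = value,
                  title = "Letter-value summary of counting errors") +
    ggplot2::theme_minimal()
}

#' Box plots of predicted vs. expected counts
#'
#' One box of predicted counts per observed true-count value, faceted by
#' organ; the dashed line marks perfect prediction.
#'
#' @param truth,predicted Tidy count tibbles over matched specimens.
#' @return A ggplot object.
#' @export
plot_predicted_counts <- function(truth, predicted) {
  joined <- counting_error(truth, predicted)
  ggplot2::ggplot(joined,
                  ggplot2::aes(x = factor(.data$true), y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = -1, linetype = "dashed",
                         color = "grey50") +
    ggplot2::geom_boxplot(outlier.shape = 1, fill = "grey90") +
    ggplot2::facet_wrap(~ .data$organ, scales = "free") +
    ggplot2::labs(x = "true count", y = "predicted count",
                  title = "Predicted vs. expected counts") +
    ggplot2::theme_minimal()
}

#' Composition bar chart of a structure dataset
#'
#' @param composition Output of [composition_summary()].
#' @return A ggplot object.
#' @export
plot_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = .data$organ, y = .data$total,
                               fill = .data$organ)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", .data$percent)), vjust = -0.3) +
    ggplot2::labs(x = NULL, y = "structures",
                  title = "Dataset composition by organ") +
    ggplot2::theme_minimal()
}

#' @rdname plot_letter_values
#' @param object A `scenario_report`.
#' @param ... Unused.
#' @method autoplot scenario_report
#' @export
autoplot.scenario_report <- function(object, ...) {
  plot_letter_values(object$errors)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
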