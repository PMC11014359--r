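#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

tail_class_fill <- ggplot2::scale_fill_manual(values = c(
  A = "#4daf4a", AU = "#377eb8", U = "#e41a1c", NONE = "#999999",
  OTHER = "#f5c710"), name = "tail class")

#' Stacked-bar plot of tail-class fractions
#'
#' @param object a `tail_summary`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.tail_summary <- function(object, ...) {
  df <- object$classes |>
    filter(.data$tail_class %in% TAIL_CLASSES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$fraction,
                                   fill = .data$tail_class)) +
    ggplot2::geom_col(position = "stack") +
    tail_class_fill +
    ggplot2::facet_wrap(stats::as.formula(paste("~", object$stratum))) +
    ggplot2::labs(x = NULL, y = "fraction of molecules") +
    ggplot2::theme_minimal()
}

#' Per-length tail histogram plot
#'
#' Bars over tail lengths 1..window with the terminal ">= window + 1"
#' censored category.
#'
#' @param summary a `tail_summary`.
#' @param tail_class `"A"` or `"AU"`.
#' @return a ggplot object.
#' @export
plot_length_hist <- function(summary, tail_class = c("A", "AU")) {
  tail_class <- match.arg(tail_class)
  df <- if (tail_class == "A") summary$hist_a else summary$hist_au
  keep <- seq(0, 100, by = 10)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$n)) +
    ggplot2::geom_col(fill = "#377eb8") +
    ggplot2::facet_grid(stats::as.formula(paste("sample ~",
                                                summary$stratum))) +
    ggplot2::scale_x_discrete(
      breaks = function(x) x[seq_along(x) %% 10 == 1 | seq_along(x) == length(x)]) +
    ggplot2::labs(x = sprintf("%s-tail length (nt)", tail_class),
                  y = "molecules") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Tail-class composition across 10-nt total-length bins
#'
#' @param summary a `tail_summary`.
#' @return a ggplot object.
#' @export
plot_ten_nt_bins <- function(summary) {
  ggplot2::ggplot(summary$ten_nt,
                  ggplot2::aes(x = .data$bin, y = .data$fraction,
                               fill = .data$tail_class)) +
    ggplot2::geom_col(position = "stack") +
    tail_class_fill +
    ggplot2::facet_grid(stats::as.formula(paste("sample ~",
                                                summary$stratum))) +
    ggplot2::labs(x = "total tail length (10-nt bins)",
                  y = "fraction of tailed molecules") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
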