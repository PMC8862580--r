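#' Plot SV counts by class
#'
#' Bar chart of call counts per SV class, the usual overview of a
#' whole-genome-alignment call set.
#'
#' @param calls SV call tibble.
#' @return A ggplot object.
#' @export
plot_sv_categories <- function(calls) {
  df <- dplyr::count(calls, .data$sv_type)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$sv_type, -.data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "#2b8cbe") +
    ggplot2::labs(x = NULL, y = "calls") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
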