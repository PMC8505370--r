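#' Scatter plot of a community metric against sown species richness
#'
#' Points per plot with (optionally) the response on its ledger scale and a
#' least-squares trend in log sown richness, the same scale on which the
#' mixed models test the effect.
#'
#' @param data Tibble with `sown_richness` and the response column (e.g.
#'   [compute_indices()] joined to a roster).
#' @param response Name of the response column.
#' @param transforms Transformation ledger applied to the y axis
#'   (`NULL` for raw values).
#' @return A ggplot.
#' @export
plot_richness_effect <- function(data, response,
                                 transforms = default_transforms()) {
  y <- data[[response]]
  lab <- response
  if (!is.null(transforms)) {
    tag <- transforms$transform[match(response, transforms$response)]
    if (!is.na(tag) && tag != "identity") {
      y <- transform_response(y, response, transforms)
      lab <- paste0(tag, "(", response, ")")
    }
  }
  df <- tibble(sown_richness = data$sown_richness, y = y)
  ggplot2::ggplot(df, ggplot2::aes(.data$sown_richness, .data$y)) +
    ggplot2::geom_jitter(width = 0.04, height = 0, alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ log(x), se = TRUE,
                         linewidth = 0.6) +
    ggplot2::scale_x_continuous(trans = "log",
                                breaks = sort(unique(df$sown_richness))) +
    ggplot2::labs(x = "sown plant species richness", y = lab) +
    ggplot2::theme_minimal()
}
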