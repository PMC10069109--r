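#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot spectra
#'
#' Absorbance (or standardized absorbance) against wavenumber, one line
#' per spectrum, wavenumber axis reversed as is conventional for FTIR.
#'
#' @param object A [spectra_matrix].
#' @param max_rows At most this many spectra are drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectra_matrix <- function(object, max_rows = 50, ...) {
  rows <- seq_len(min(nrow(object$values), max_rows))
  df <- purrr::map_dfr(rows, function(i) {
    tibble::tibble(cow_id = object$cow_id[i],
                   replicate = object$replicate[i],
                   wavenumber = object$wavenumbers,
                   value = object$values[i, ])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$value,
                                   group = interaction(.data$cow_id,
                                                       .data$replicate))) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "wavenumber (cm⁻¹)",
                  y = if (object$standardized) "standardized absorbance"
                  else object$unit) +
    ggplot2::theme_minimal()
}

#' Plot variable importance across the wavelength axis
#'
#' @param object A fitted [gbm_fit()] ensemble.
#' @param threshold Horizontal reference at the significance threshold
#'   (percent of phenotypic variability; default 0.8).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gbm_fit <- function(object, threshold = 0.8, ...) {
  vi <- variable_importance(object)
  vi$index <- seq_len(nrow(vi))
  ggplot2::ggplot(vi, ggplot2::aes(.data$index, .data$vi)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$index, yend = 0),
                          linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        colour = "red3") +
    ggplot2::labs(x = "feature index", y = "variable importance (%)") +
    ggplot2::theme_minimal()
}

#' Bar chart of relative differences versus the FTIR-only baseline
#'
#' @param rd Output of [rd_table()].
#' @return A ggplot object faceted by scheme and method.
#' @export
plot_rd <- function(rd) {
  ggplot2::ggplot(rd, ggplot2::aes(.data$trait, .data$rd,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$method),
                        cols = ggplot2::vars(.data$scheme)) +
    ggplot2::labs(x = NULL, y = "relative difference vs M1 (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Relative difference against heritability
#'
#' Scatter of per-trait relative differences (M4 vs M1) on heritability
#' estimates with the OLS fit of [rd_vs_h2_regression()].
#'
#' @param rd_per_trait,h2_per_trait Matching numeric vectors.
#' @param labels Optional trait labels.
#' @return A ggplot object.
#' @export
plot_rd_vs_h2 <- function(rd_per_trait, h2_per_trait, labels = NULL) {
  df <- tibble::tibble(rd = rd_per_trait, h2 = h2_per_trait,
                       label = labels %||% as.character(seq_along(rd_per_trait)))
  ggplot2::ggplot(df, ggplot2::aes(.data$h2, .data$rd)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.6,
                       size = 3) +
    ggplot2::labs(x = "heritability", y = "relative difference M4 vs M1 (%)") +
    ggplot2::theme_minimal()
}
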