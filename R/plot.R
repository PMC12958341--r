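#' Plot a spectrum
#'
#' Standard NMR presentation: intensity against a reversed ppm axis.
#'
#' @param object a `qnmr_spectrum`
#' @param region optional length-2 ppm interval to zoom into
#' @param ... unused
#' @return a ggplot object
#' @method autoplot qnmr_spectrum
#' @export
autoplot.qnmr_spectrum <- function(object, region = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(region)) {
    df <- dplyr::filter(df, .data$ppm >= min(region), .data$ppm <= max(region))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ppm, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot per-compound yields
#'
#' @param object a `qnmr_result`
#' @param ... unused
#' @return a ggplot bar chart of wt% yields, unreliable compounds hatched
#'   out by transparency
#' @method autoplot qnmr_result
#' @export
autoplot.qnmr_result <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::filter(df, !is.na(.data$yield_wt_pct))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$compound, -.data$yield_wt_pct),
    y = .data$yield_wt_pct, fill = .data$cls, alpha = .data$reliable
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.4),
                                guide = "none") +
    ggplot2::labs(x = NULL, y = "yield (wt %)", fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot an NMR-versus-reference comparison
#'
#' @param object a `qnmr_comparison`
#' @param ... unused
#' @return a ggplot scatter of NMR against reference yields, faceted by
#'   compound, with the identity line
#' @method autoplot qnmr_comparison
#' @export
autoplot.qnmr_comparison <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$ref_yield, y = .data$nmr_yield)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~compound, scales = "free") +
    ggplot2::labs(x = "reference yield (wt %)", y = "NMR yield (wt %)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
plot.qnmr_spectrum <- function(x, ...) print(autoplot.qnmr_spectrum(x, ...))

#' @export
plot.qnmr_comparison <- function(x, ...) print(autoplot.qnmr_comparison(x, ...))
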