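#' Plot per-strain induction profiles against the library thresholds
#'
#' Scatter of uninduced versus induced per-strain means (log-log), coloured
#' by induction class, with the library-wide classification bounds drawn as
#' dashed lines: strains right of the vertical line have elevated
#' background (semi-constitutive candidates), strains below the horizontal
#' line are induction-impaired.
#'
#' @param summaries Classified summaries from [classify_induction()].
#' @param thresholds The matching [induction_thresholds()] object.
#' @return A ggplot object.
#' @export
plot_induction <- function(summaries, thresholds) {
  stopifnot(inherits(thresholds, "alascan_thresholds"))
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$mean_uninduced,
                               y = .data$mean_induced,
                               colour = .data$induction_class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = thresholds$upper_uninduced,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = thresholds$lower_induced,
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean uninduced fluorescence (a.u.)",
                  y = "mean induced fluorescence (a.u.)",
                  colour = "induction class") +
    ggplot2::theme_minimal()
}

#' Effect-table plot: fluorescence ratio versus abundance ratio
#'
#' Each mutant is placed by its abundance ratio A (x) and fluorescence
#' ratio F (y) on log scales. The shaded vertical strip is the abundance
#' null band; the solid diagonal is exact proportionality (F = A) and the
#' dotted diagonal the proportionality threshold (F = lower bound x A)
#' below which an abundance-impaired, induction-impaired mutant is called a
#' combined signaling-and-abundance defect.
#'
#' @param object An `alascan_effects` table from [assemble_effect_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot alascan_effects
#' @export
autoplot.alascan_effects <- function(object, ...) {
  band <- attr(object, "band")
  df <- dplyr::filter(as_tibble(object), !is.na(.data$abundance_ratio))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abundance_ratio,
                                   y = .data$fluorescence_ratio,
                                   colour = .data$category)) +
    ggplot2::annotate("rect", xmin = band$lower, xmax = band$upper,
                      ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(slope = 1, intercept = log10(band$lower),
                         linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.85) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "abundance ratio A (mutant / wild-type)",
                  y = "fluorescence ratio F (mutant / wild-type)",
                  colour = "effect category") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
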