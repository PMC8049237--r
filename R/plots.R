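# ggplot2 views of the result types ---------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scree plot of a shape model
#'
#' @param object a [fit_ssm()] model.
#' @param ... unused.
#' @return a ggplot: per-mode and cumulative explained variance.
#' @export
autoplot.shape_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode)) +
    ggplot2::geom_col(ggplot2::aes(y = 100 * .data$explained_variance_ratio),
                      fill = "grey35") +
    ggplot2::geom_line(ggplot2::aes(y = 100 * .data$cumulative_variance),
                       colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = 100 * .data$cumulative_variance),
                        colour = "firebrick") +
    ggplot2::labs(x = "shape mode", y = "explained variance (%)",
                  title = "Shape model variance spectrum") +
    ggplot2::theme_minimal()
}

#' Pressure-volume and time-course view of a simulated beat
#'
#' @param object a [simulate_beat()] trace.
#' @param ... unused.
#' @return a ggplot of the PV loop per ventricle.
#' @export
autoplot.beat_trace <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$volume, y = .data$pressure,
                               colour = .data$ventricle)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "cavity volume (mL)", y = "cavity pressure (mmHg)",
                  title = "Simulated pressure-volume loops") +
    ggplot2::theme_minimal()
}

#' Sobol share chart (doughnut-style stacked bar)
#'
#' @param object a [sobol_saltelli()] result.
#' @param ... unused.
#' @return a ggplot of first-order shares plus the multifactorial remainder.
#' @export
autoplot.sobol_result <- function(object, ...) {
  df <- tidy(object)
  df$share <- pmax(0, df$share)
  ggplot2::ggplot(df, ggplot2::aes(x = 1, y = .data$share,
                                   fill = .data$input)) +
    ggplot2::geom_col(width = 0.4, colour = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::xlim(0.4, 1.3) +
    ggplot2::labs(title = "First-order Sobol' shares",
                  fill = NULL, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Mode-phenotype correlation heatmap
#'
#' @param x a [mode_phenotype_correlations()] result.
#' @return a ggplot tile matrix of Pearson R.
#' @export
plot_correlation_heatmap <- function(x) {
  ggplot2::ggplot(x$correlations,
                  ggplot2::aes(x = .data$phenotype, y = .data$mode,
                               fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue4",
                                  mid = "white", high = "firebrick3") +
    ggplot2::labs(x = NULL, y = NULL, fill = "R") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Local sensitivity tile matrix
#'
#' @param x an [lsa_battery()] result.
#' @return a ggplot tile matrix of sensitivity coefficients.
#' @export
plot_lsa <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$phenotype, y = .data$parameter,
                                  fill = .data$sc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue4", mid = "white",
                                  high = "firebrick3") +
    ggplot2::labs(x = NULL, y = NULL, fill = "SC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Normalised-range bar chart
#'
#' @param x a [normalized_range_filter()] result.
#' @param threshold threshold line to draw (default 0.2).
#' @return a ggplot bar chart with the discard threshold marked.
#' @export
plot_normalized_range <- function(x, threshold = 0.2) {
  ggplot2::ggplot(x, ggplot2::aes(x = stats::reorder(.data$phenotype,
                                                     .data$norm_range),
                                  y = .data$norm_range,
                                  fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalised range (range / mean)",
                  fill = "retained") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
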