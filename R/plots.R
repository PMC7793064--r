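# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Percentile curves by class
#'
#' Per-patient percentile curves for one or more markers, coloured by
#' relapse class.
#'
#' @param features A `percentile_tbl`.
#' @param markers Markers to show; default all.
#' @return A ggplot.
#' @export
plot_percentile_curves <- function(features, markers = NULL) {
  d <- features
  if (!is.null(markers)) d <- d[d$marker %in% markers, ]
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$level, y = .data$value,
    group = .data$patient_id, colour = .data$label)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~marker) +
    ggplot2::scale_colour_manual(
      values = c(N = "#2166ac", R = "#b2182b"), na.value = "grey50") +
    ggplot2::labs(x = "percentile", y = "normalised intensity",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' @method autoplot fisher_model
#' @export
autoplot.fisher_model <- function(object, ...) {
  d <- object$features
  ggplot2::ggplot(d, ggplot2::aes(x = .data$marker, y = .data$level,
                                  fill = .data$fr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "FR") +
    ggplot2::labs(x = NULL, y = "percentile",
                  title = "Fisher's Ratio matrix") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "value",
                  title = paste0("Cross-validated performance (",
                                 object$scheme, ")")) +
    ggplot2::theme_minimal()
}

#' @method autoplot feature_frequency
#' @export
autoplot.feature_frequency <- function(object, ...) {
  ggplot2::ggplot(object$frequencies,
                  ggplot2::aes(x = stats::reorder(.data$marker,
                                                  .data$frequency),
                               y = .data$frequency)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~threshold,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "usage frequency") +
    ggplot2::theme_minimal()
}

#' @method autoplot correlation_report
#' @export
autoplot.correlation_report <- function(object, ...) {
  d <- object$pairs
  ggplot2::ggplot(d, ggplot2::aes(x = .data$var1, y = .data$var2,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$p), "",
                     formatC(.data$p, digits = 2, format = "g"))),
      size = 2.5) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1),
                                  na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Pearson r (fill) with p-values (text)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
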