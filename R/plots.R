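#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot the MCR-versus-panel-size curve
#'
#' Line of the median misclassification error against candidate panel size
#' with a ribbon for the 95% interval on the median.
#'
#' @param object A `gene_panel_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gene_panel_cv
#' @export
autoplot.gene_panel_cv <- function(object, ...) {
  ev <- object$evaluations
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$panel_size, y = .data$median_mcr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         fill = "lightblue", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Number of genes", y = "Median MCR",
                  title = "Monte-Carlo cross-validated panel reduction") +
    ggplot2::theme_minimal()
}

#' Plot a subtype-call distribution
#'
#' @param object A `subtype_calls` tibble.
#' @param ... Unused.
#' @return A ggplot bar chart of assigned subtypes (incl. undetermined).
#' @method autoplot subtype_calls
#' @export
autoplot.subtype_calls <- function(object, ...) {
  d <- subtype_distribution(object)
  d$subtype <- factor(d$subtype, d$subtype)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$subtype, y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of samples") +
    ggplot2::theme_minimal()
}

#' Plot per-sample subtype mixture proportions
#'
#' Stacked bars of the SVR-derived subtype proportions per sample, the
#' single-sample analogue of a deconvolution summary plot.
#'
#' @param object An `idsample_weights` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot idsample_weights
#' @export
autoplot.idsample_weights <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$subtype <- factor(d$subtype, unique(d$subtype))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$proportion,
                                  fill = .data$subtype)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.7, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Subtype proportion", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot lane QC metrics
#'
#' @param object A `nano_qc` tibble.
#' @param ... Unused.
#' @return A ggplot object of the four QC metrics per sample, flagged lanes
#'   highlighted.
#' @method autoplot nano_qc
#' @export
autoplot.nano_qc <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("sample_id", "fov_fraction", "binding_density",
                                "positive_control_r2", "background", "flags")],
    cols = -c("sample_id", "flags"), names_to = "metric", values_to = "value")
  d$flagged <- d$flags != ""
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$value,
                                  colour = .data$flagged)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = "flagged") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
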