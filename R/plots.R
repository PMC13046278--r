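# ggplot2 visualizations for the main result types.

#' @rdname autoplot-iohcast
#' @name autoplot-iohcast
#' @title Plot methods for iohcast result objects
#' @param object Result object.
#' @param ... Unused.
NULL

#' Reliability diagram for a calibration report
#'
#' Mean predicted probability against observed event frequency per bin,
#' point size proportional to bin weight, with the identity (perfect
#' calibration) as a dashed reference.
#'
#' @param object A `calibration_report` from [ece()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_report <- function(object, ...) {
  bins <- filter(object$bins, .data$n > 0)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$confidence, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight), colour = "#2166ac") +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted probability",
                  y = "Observed IOH frequency",
                  title = sprintf("ECE %.4f (%.4f, %.4f)", object$ece,
                                  object$ci_lo, object$ci_hi)) +
    ggplot2::theme_minimal()
}

#' ROC curve(s)
#'
#' @param y Binary labels.
#' @param p Probabilities, or a named list of probability vectors to
#'   overlay several models.
#' @return A ggplot object.
#' @export
plot_roc_curve <- function(y, p) {
  if (!is.list(p)) p <- list(model = p)
  df <- purrr::imap_dfr(p, function(pp, nm) {
    ord <- order(pp, decreasing = TRUE)
    ys <- as.integer(y)[ord]
    tibble(model = nm,
           fpr = c(0, cumsum(1 - ys) / sum(1 - ys)),
           tpr = c(0, cumsum(ys) / sum(ys)))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}

#' MAP trace with predicted IOH risk panels
#'
#' Mirrors the alert-simulation figure layout: the observed MAP trajectory
#' on top (hypotensive minutes highlighted, threshold line at the event
#' definition) and one panel of predicted risk with its decision threshold.
#'
#' @param trajectory A [rolling_predict()] trajectory for one case.
#' @param threshold Decision threshold (or `threshold_choice`).
#' @param map_threshold MAP event threshold in mmHg (default 65).
#' @return A ggplot object (faceted).
#' @export
plot_trajectory <- function(trajectory, threshold, map_threshold = 65) {
  if (inherits(threshold, "threshold_choice")) threshold <- threshold$threshold
  long <- bind_rows(
    tibble(t = trajectory$t_end, value = trajectory$map, panel = "MAP (mmHg)",
           ref = map_threshold),
    tibble(t = trajectory$t_end, value = trajectory$p,
           panel = sprintf("Predicted IOH risk (h = %s min)",
                           attr(trajectory, "horizon")),
           ref = threshold)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$ref),
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Minutes from case start", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of burden odds ratios
#'
#' @param fits A list of `burden_fit` objects (e.g. per threshold/outcome).
#' @return A ggplot object.
#' @export
plot_burden_forest <- function(fits) {
  df <- bind_rows(purrr::map(fits, function(f) f$result))
  df$label <- sprintf("%s, MAP ≤%g", toupper(df$outcome), df$threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                            height = 0.15) +
    ggplot2::geom_point(size = 2, colour = "#b2182b") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio per 60 mmHg·min (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' AKI to AKD transition (Sankey-style) plot
#'
#' Tile rendering of the [transition_table()] counts: AKI stage on the
#' left axis, AKD stage on the bottom, tile area shaded by patient count.
#'
#' @param transitions A [transition_table()] tibble.
#' @return A ggplot object.
#' @export
plot_transitions <- function(transitions) {
  ggplot2::ggplot(transitions,
                  ggplot2::aes(x = factor(.data$akd_stage),
                               y = factor(.data$aki_stage),
                               fill = .data$n)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "#f7fbff", high = "#08306b") +
    ggplot2::labs(x = "AKD stage (days 8-90)", y = "AKI stage (days 0-7)",
                  fill = "Patients") +
    ggplot2::theme_minimal()
}
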