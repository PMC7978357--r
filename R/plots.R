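#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a kinetic fit
#'
#' Velocity observations and fitted rate-law curves, one colour per
#' inhibitor level, on a log substrate axis.
#'
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  data <- object$data
  levels_i <- sort(unique(data$inhibitor_uM))
  s_grid <- exp(seq(log(min(data$substrate_uM)), log(max(data$substrate_uM)),
                    length.out = 100))
  curves <- tidyr::expand_grid(substrate_uM = s_grid, inhibitor_uM = levels_i)
  curves$velocity <- velocity(object$params, curves$substrate_uM,
                              curves$inhibitor_uM)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$substrate_uM,
                                     y = .data$velocity,
                                     colour = factor(.data$inhibitor_uM))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curves) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "substrate (µM)", y = "velocity",
                  colour = "inhibitor (µM)",
                  title = paste0("Global ", object$mechanism, " fit")) +
    ggplot2::theme_minimal()
}

#' Plot a dose-response fit
#'
#' Observed responses and the fitted four-parameter logistic, with the IC50
#' marked. Zero doses are drawn at half the smallest positive dose so they
#' survive the log axis.
#'
#' @param object A `dose_response_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  data <- object$data
  pos <- data$dose[data$dose > 0]
  anchor <- min(pos) / 2
  data$dose_plot <- ifelse(data$dose == 0, anchor, data$dose)
  d_grid <- exp(seq(log(anchor), log(max(pos)), length.out = 200))
  curve <- tibble::tibble(
    dose_plot = d_grid,
    response = logistic4(d_grid, object$ic50, object$hill, object$top,
                         object$bottom)
  )
  ggplot2::ggplot(data, ggplot2::aes(x = .data$dose_plot, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curve) +
    ggplot2::geom_vline(xintercept = object$ic50, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose", y = "response",
                  title = sprintf("4PL fit, IC50 = %.3g", object$ic50)) +
    ggplot2::theme_minimal()
}

#' Plot a banded fitness-score distribution
#'
#' Histogram of per-gene scores with the percentile cutoffs marked, the view
#' used to call depleted and enriched genes in transposon-library screens.
#'
#' @param scores Banded score tibble from [classify_percentiles()].
#' @return A ggplot.
#' @export
plot_score_bands <- function(scores) {
  stopifnot(all(c("score", "band") %in% names(scores)))
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$score, fill = .data$band)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.9) +
    ggplot2::geom_vline(xintercept = c(attr(scores, "cutoff_low"),
                                       attr(scores, "cutoff_high")),
                        linetype = "dashed") +
    ggplot2::labs(x = "log2 normalized treated/control", y = "genes",
                  fill = "band") +
    ggplot2::theme_minimal()
}

#' Plot z-scores of a chemical-genetic screen
#'
#' Rank plot of per-strain sensitivity z-scores with the calling threshold.
#'
#' @param zscores Tibble from [compute_zscores()].
#' @param threshold Threshold line to draw (default 1.88).
#' @return A ggplot.
#' @export
plot_zscreen <- function(zscores, threshold = 1.88) {
  stopifnot(all(c("strain", "z", "sensitive") %in% names(zscores)))
  zscores <- dplyr::mutate(dplyr::arrange(zscores, dplyr::desc(.data$z)),
                           rank = dplyr::row_number())
  ggplot2::ggplot(zscores, ggplot2::aes(x = .data$rank, y = .data$z,
                                        colour = .data$sensitive)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "strain rank", y = "sensitivity z-score",
                  colour = "sensitive") +
    ggplot2::theme_minimal()
}
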