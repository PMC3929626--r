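#' Histogram of PSI ratios with the exclusion window
#'
#' Distribution of exon-level PSI ratios (KO/CTRL) on a log2 axis, with the
#' grey exclusion window (defaults 2/3 to 1.5) shaded: exons inside it are
#' considered unchanged and are excluded by the screen.
#'
#' @param cands Candidate tibble with a `psi_ratio` column.
#' @param low_cut,high_cut Window bounds.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_psi_distribution <- function(cands, low_cut = 2 / 3, high_cut = 1.5,
                                  bins = 60) {
  ggplot2::ggplot(cands, ggplot2::aes(x = log2(.data$psi_ratio))) +
    ggplot2::annotate("rect", xmin = log2(low_cut), xmax = log2(high_cut),
                      ymin = -Inf, ymax = Inf, fill = "grey80",
                      alpha = 0.6) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "grey30", linewidth = 0.1) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "log2 PSI ratio (KO / CTRL)", y = "exons",
                  title = "Exon inclusion changes",
                  subtitle = "shaded: excluded window of unchanged inclusion") +
    ggplot2::theme_minimal()
}

#' Volcano plot of transcript-level differential expression
#'
#' Signed moderated-t results with the fold and p thresholds of the DE
#' call drawn in.
#'
#' @param de_table Tibble from [moderated_t_table()].
#' @param fold_cut,p_cut Call thresholds (defaults 1.5 and 0.05).
#' @return A ggplot object.
#' @export
plot_volcano <- function(de_table, fold_cut = 1.5, p_cut = 0.05) {
  de_table <- de_table |>
    dplyr::mutate(called = abs(.data$fold_change) >= fold_cut &
                    .data$p_value <= p_cut)
  ggplot2::ggplot(de_table,
                  ggplot2::aes(x = .data$log2_fc,
                               y = -log10(.data$p_value),
                               colour = .data$called)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-log2(fold_cut), log2(fold_cut)),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(p_cut), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = "called DE") +
    ggplot2::labs(x = "log2 fold change (KO / CTRL)", y = "-log10 p",
                  title = "Transcript-level differential expression") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_psi_distribution Autoplot method for screen results:
#'   PSI distribution of all screened exons at the configured window.
#' @param object A `screen_result`.
#' @param ... Passed on to [plot_psi_distribution()].
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.screen_result <- function(object, ...) {
  plot_psi_distribution(object$all_candidates,
                        low_cut = object$config$psi_low_cut,
                        high_cut = object$config$psi_high_cut, ...)
}

#' @describeIn plot_volcano Autoplot method for moderated-t fits.
#' @param object A `mod_t_fit`.
#' @param ... Passed on to [plot_volcano()].
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.mod_t_fit <- function(object, ...) {
  plot_volcano(tidy(object), ...)
}
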