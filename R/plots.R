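#' Volcano plot of a differential-abundance test
#'
#' @param object A `barseq_test` tibble from [exact_nb_test()].
#' @param fdr Highlight threshold on q-values.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.barseq_test <- function(object, fdr = 0.05, ...) {
  df <- mutate(object, significant = .data$q_value <= fdr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logFC,
                                   y = -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = sprintf("q <= %g", fdr))
}

#' Variance-component bar chart
#'
#' @param object A `barseq_variance` row from [partition_variance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.barseq_variance <- function(object, ...) {
  df <- tidyr::pivot_longer(object[, c("treatment", "biological",
                                       "technical")],
                            dplyr::everything(),
                            names_to = "component", values_to = "share")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$share,
                                   fill = .data$component)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x)) +
    ggplot2::labs(x = NULL, y = "share of variance")
}

#' Smoothed design-evaluation curves
#'
#' One panel per metric, one curve per design, against the subsampling
#' fraction.
#'
#' @param object A `barseq_design_eval` object.
#' @param metrics Metrics to show (default the four headline metrics).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.barseq_design_eval <- function(object,
                                        metrics = c("n_significant",
                                                    "mse_logfc",
                                                    "n_significant_gene_sets",
                                                    "empirical_fdr"), ...) {
  df <- object$curves |> filter(.data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$value,
                                   colour = .data$design)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "fraction of reads", y = NULL, colour = "design")
}

#' Power curves stratified by effect size
#'
#' @param x A `barseq_design_eval` object.
#' @param design Design label to show (default the first).
#' @return A ggplot object.
#' @export
plot_power_by_effect <- function(x, design = x$designs[1]) {
  df <- x$curves |>
    filter(.data$design == !!design,
           .data$metric %in% c("power_all", "power_fc1.5", "power_fc2"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$value,
                                   linetype = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.9, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "fraction of reads", y = "power",
                  linetype = "stratum", title = design)
}
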