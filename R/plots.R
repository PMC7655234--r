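# Summary plots for the training-size experiment.

#' Training-size curves of the fold-averaged DFE
#'
#' One line per model: pooled mean (or 95th percentile) DFE within a mask as
#' a function of the number of training images, averaged over the four
#' cross-validation folds. The no-model baseline is drawn as a horizontal
#' reference line.
#'
#' @param results Results table from [run_experiment()].
#' @param mask "evaluation" or "tumour".
#' @param statistic "pooled_mean_mm" or "pooled_p95_mm".
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_training_curves <- function(results, mask = "evaluation",
                                 statistic = "pooled_mean_mm") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_training_curves requires the ggplot2 package", call. = FALSE)
  }
  fa <- attr(results, "fold_averaged")
  if (is.null(fa)) stop("results carry no fold-averaged summary", call. = FALSE)
  fa <- fa[fa$mask == mask, ]
  base <- results[results$model == "no_model" & results$mask == mask, ]
  nsig <- vapply(strsplit(fa$model, "[+_]"), length, 1L)
  fa$signals <- ifelse(grepl("pc1_pc2_pc3|deriv\\+|\\+deriv\\+", fa$model) |
                         nsig >= 4, "3-signal", "2-signal")
  ggplot2::ggplot(fa, ggplot2::aes(x = .data$n_train, y = .data[[statistic]],
                                   colour = .data$model,
                                   linetype = .data$signals)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = base[[statistic]], linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "training images", y = paste("DFE", statistic, "(mm)"),
                  title = sprintf("DFE vs training-set size (%s mask)", mask)) +
    ggplot2::theme_minimal()
}
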