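# ggplot2 displays for the standard result types.

#' Volcano plot of differential abundance results
#'
#' Mean log2FC against -log10 p-value, coloured by species when available,
#' with the significance cutoffs as dashed lines.
#'
#' @param results A `diasis_diff` tibble, ideally classified.
#' @param p_cut,fc_cut Cutoff lines; default to the attributes stored by
#'   [classify_hits()], falling back to 0.01 and 1.
#' @return A ggplot object, faceted by comparison.
#' @export
plot_volcano <- function(results, p_cut = NULL, fc_cut = NULL) {
  p_cut <- p_cut %||% attr(results, "p_cut") %||% 0.01
  fc_cut <- fc_cut %||% attr(results, "fc_cut") %||% 1
  d <- tibble::as_tibble(results)
  d <- d[!is.na(d$p_value), , drop = FALSE]
  has_species <- "species" %in% names(d) && !all(is.na(d$species))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_log2fc,
                                       y = -log10(.data$p_value)))
  p <- if (has_species) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$species),
                            alpha = 0.5, size = 0.8)
  } else {
    p + ggplot2::geom_point(alpha = 0.5, size = 0.8)
  }
  p +
    ggplot2::geom_vline(xintercept = c(-fc_cut, fc_cut), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(p_cut), linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$comparison)) +
    ggplot2::labs(x = "mean log2 fold change", y = "-log10 p-value") +
    ggplot2::theme_bw()
}

#' @method autoplot diasis_diff
#' @export
autoplot.diasis_diff <- function(object, ...) {
  plot_volcano(object, ...)
}

#' Precision-recall curves
#'
#' @param pr A PR tibble from [precision_recall()] (one or both rankings).
#' @return A ggplot object.
#' @export
plot_pr_curve <- function(pr) {
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$recall, y = .data$precision,
                                   colour = .data$ranking)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::facet_wrap(ggplot2::vars(.data$comparison)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision") +
    ggplot2::theme_bw()
}

#' Replicate completeness bars
#'
#' @param comp A completeness tibble from [completeness()].
#' @return A ggplot object: protein counts per replicate-coverage bin,
#'   faceted by species.
#' @export
plot_completeness <- function(comp) {
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$sample, y = .data$n_proteins,
                                     fill = factor(.data$n_replicates))) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(ggplot2::vars(.data$species)) +
    ggplot2::labs(x = "sample", y = "proteins",
                  fill = "replicates\ndetected") +
    ggplot2::theme_bw()
}
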