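#' Plot a persistence diagram
#'
#' Births against deaths per homological dimension, with the diagonal drawn
#' and the essential class marked at a capped ordinate labelled infinity.
#'
#' @param diag A `persistence_diagram`.
#' @param file Optional output path (PNG/SVG by extension); `NULL` returns
#'   the ggplot object only.
#' @return A ggplot object, invisibly if written to file.
#' @export
plot_diagram <- function(diag, file = NULL) {
  df <- as.data.frame(diag)
  finite <- df[is.finite(df$death), , drop = FALSE]
  lims <- range(c(0, finite$birth, finite$death, df$birth))
  cap <- lims[2] + 0.1 * max(1, diff(lims))
  df$death_plot <- ifelse(is.finite(df$death), df$death, cap)
  df$dim <- factor(df$dim, levels = c(0, 1), labels = c("H0", "H1"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$birth, y = .data$death_plot,
                                        colour = .data$dim,
                                        shape = .data$dim)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(H0 = "#2166ac", H1 = "#1a9850")) +
    ggplot2::labs(x = "birth", y = "death", colour = NULL, shape = NULL,
                  title = "Persistence diagram") +
    ggplot2::theme_minimal()
  if (any(df$essential))
    p <- p + ggplot2::annotate("text", x = df$birth[df$essential],
                               y = cap, label = "∞", vjust = -0.3)
  if (!is.null(file)) { save_figure(p, file); return(invisible(p)) }
  p
}

#' Plot a patch score map
#'
#' Heat map of one panel statistic over the patch grid of a source image;
#' tiles without a patch (discarded background) are drawn distinctly.
#'
#' @param scores Numeric matrix from [score_patches()].
#' @param statistic Label for the fill scale.
#' @inheritParams plot_diagram
#' @export
plot_scoremap <- function(scores, statistic = "score", file = NULL) {
  df <- expand.grid(patch_row = seq_len(nrow(scores)),
                    patch_col = seq_len(ncol(scores)))
  df$value <- scores[cbind(df$patch_row, df$patch_col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$patch_col,
                                        y = .data$patch_row,
                                        fill = .data$value)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "patch column", y = "patch row", fill = statistic) +
    ggplot2::theme_minimal()
  if (!is.null(file)) { save_figure(p, file); return(invisible(p)) }
  p
}

significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"))
}

#' Box plots of one statistic per group
#'
#' Per-group box plots (median, quartiles, outliers beyond 1.5 IQR) of a
#' panel statistic, optionally annotated with a significance star bracket
#' from an adjusted p-value: 'ns' for p > 0.05, then '*', '**', '***',
#' '****' at 0.05, 0.01, 0.001 and 0.0001.
#'
#' @param panels Panel data frame with the grouping column.
#' @param statistic One of [panel_stats()].
#' @param group Name of the grouping column (e.g. `"genotype"`).
#' @param p_adjusted Optional adjusted p-value to annotate.
#' @inheritParams plot_diagram
#' @export
plot_group_boxes <- function(panels, statistic, group = "genotype",
                             p_adjusted = NULL, file = NULL) {
  if (!statistic %in% names(panels))
    stop("unknown statistic '", statistic, "'; valid names: ",
         paste(panel_stats(), collapse = ", "))
  df <- data.frame(value = panels[[statistic]],
                   group = factor(panels[[group]]))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                        fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 1, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = statistic) +
    ggplot2::theme_minimal()
  if (!is.null(p_adjusted)) {
    ytop <- max(df$value, na.rm = TRUE)
    p <- p + ggplot2::annotate("text", x = mean(seq_len(nlevels(df$group))),
                               y = ytop + 0.05 * max(1, abs(ytop)),
                               label = as.character(significance_stars(p_adjusted)))
  }
  if (!is.null(file)) { save_figure(p, file); return(invisible(p)) }
  p
}

save_figure <- function(p, file, width = 6, height = 4.5) {
  ggplot2::ggsave(file, plot = p, width = width, height = height, dpi = 150)
  invisible(file)
}
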