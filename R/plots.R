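# ggplot2 views of population summaries and per-cell tables.

#' Plot a population summary
#'
#' `which = "overlap"`: heatmap of median pairwise overlap `O(row|col)`;
#' `"contact"`: contact-frequency heatmap with pairing frequencies on the
#' diagonal; `"shells"`: mean radial shell profiles per channel (shell 1 =
#' periphery, shell 5 = center).
#'
#' @param object a `ct_summary` from [aggregate_cells()].
#' @param which `"overlap"`, `"contact"` or `"shells"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ct_summary <- function(object, which = c("overlap", "contact", "shells"),
                                ...) {
  which <- match.arg(which)
  if (which == "shells") {
    sp <- object$shell_profiles
    if (is.null(sp)) stop("summary has no shell profiles", call. = FALSE)
    return(
      ggplot2::ggplot(sp, ggplot2::aes(.data$shell, .data$mean_fraction,
                                       colour = .data$channel)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::labs(x = "shell (1 = periphery, 5 = center)",
                      y = "mean fraction of CT volume", colour = NULL) +
        ggplot2::theme_minimal()
    )
  }
  m <- if (which == "overlap") object$overlap else object$contact
  df <- tidy(object)
  df <- df[df$metric == if (which == "overlap") "median_overlap"
           else "contact_frequency", ]
  df$channel_a <- factor(df$channel_a, levels = rownames(m))
  df$channel_b <- factor(df$channel_b, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$channel_b, .data$channel_a,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(
      x = if (which == "overlap") "reference (denominator)" else NULL,
      y = NULL,
      fill = if (which == "overlap") "median\noverlap" else "frequency",
      title = if (which == "overlap") "Median CT overlap O(row | col)"
      else "Contact frequency (diagonal: pairing)"
    ) +
    ggplot2::theme_minimal()
}

#' Box-summary plot of a per-cell metric across channels
#'
#' @param cells tibble from [measure_cells()].
#' @param metric column prefix, e.g. `"volfrac"`, `"compacity"`,
#'   `"intermix"`.
#' @return a ggplot (Tukey-style boxes).
#' @export
plot_cell_metric <- function(cells, metric = "volfrac") {
  cols <- grep(paste0("^", metric, "_"), names(cells), value = TRUE)
  if (length(cols) == 0L) stop("no columns match metric '", metric, "'", call. = FALSE)
  long <- tidyr::pivot_longer(cells[, c("cell_id", cols)], -"cell_id",
                              names_prefix = paste0(metric, "_"),
                              names_to = "channel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$channel, .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
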