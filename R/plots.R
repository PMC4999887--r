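#' Plot a replicate-QC report
#'
#' Three panels: replicate-vs-replicate intensity scatter (log10 scale) with
#' the OLS fit, the distribution of the log2 inter-replicate ratio, and the
#' cumulative percent-variation curve with the 30% mark.
#'
#' @param object A `qc_report`.
#' @param ... Unused.
#' @return A patchwork of ggplots.
#' @exportS3Method ggplot2::autoplot
autoplot.qc_report <- function(object, ...) {
  df <- tibble(ia = object$intensity_a, ib = object$intensity_b)
  p1 <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ia, y = .data$ib)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "replicate A intensity", y = "replicate B intensity",
      subtitle = sprintf("R² = %.4f, slope = %.3f",
                         object$pearson_r2, object$regression_slope)
    )
  p2 <- ggplot2::ggplot(
    tibble(lr = log2(df$ia / df$ib)), ggplot2::aes(x = .data$lr)
  ) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::labs(
      x = "log2 replicate ratio",
      subtitle = sprintf("σ = %.3f", object$sigma_log2)
    )
  p3 <- ggplot2::ggplot(
    object$variation_curve,
    ggplot2::aes(x = .data$pct_variation, y = .data$cum_fraction)
  ) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = 30, linetype = "dashed") +
    ggplot2::coord_cartesian(xlim = c(0, 100)) +
    ggplot2::labs(x = "% variation", y = "cumulative fraction of proteins")
  patchwork::wrap_plots(p1, p2, p3, ncol = 3)
}

#' Histogram of a comparison's log2 ratios
#'
#' @param proteins Output of [compute_protein_ratios()].
#' @param comparison A [comparison()] or id string.
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_ratio_distribution <- function(proteins, comparison, bins = 60) {
  id <- if (inherits(comparison, "comparison")) comparison$id else as.character(comparison)
  col <- paste0("log2_", id)
  df <- proteins %>% filter(!is.na(.data[[col]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[col]])) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::labs(x = sprintf("log2 ratio (%s)", id), y = "proteins")
}

#' Volcano plot of DE calls
#'
#' @param de_calls Output of [call_differential()].
#' @return A ggplot (log2 ratio vs -log10 p, coloured by status).
#' @export
plot_volcano <- function(de_calls) {
  df <- de_calls %>% filter(.data$status != "not_tested")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2_ratio, y = -log10(.data$p_value), colour = .data$status
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(up = "firebrick", down = "steelblue", ns = "grey60")
    ) +
    ggplot2::labs(x = "log2 ratio", y = "-log10 p", colour = NULL)
}

#' Plot clustered expression profiles
#'
#' One line per protein across comparisons, faceted by cluster.
#'
#' @param object A `profile_clusters`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.profile_clusters <- function(object, ...) {
  long <- object$profiles %>%
    left_join(object$assignments, by = "protein_group") %>%
    tidyr::pivot_longer(
      dplyr::starts_with("log2_"),
      names_to = "comparison", values_to = "log2_ratio",
      names_prefix = "log2_"
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$comparison, y = .data$log2_ratio, group = .data$protein_group
  )) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = NULL, y = "log2 ratio")
}
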