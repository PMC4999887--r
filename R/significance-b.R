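#' Intensity-binned outlier p-values for protein ratios (Significance B)
#'
#' Reporter-ratio scatter shrinks with protein abundance, so a single global
#' null distribution over- or under-calls depending on intensity. The
#' statistic therefore sorts proteins by `summed_intensity`, partitions them
#' into consecutive bins of `bin_size`, and models the null spread of the
#' log2 ratio within each bin robustly from percentiles: with bin median
#' `m`, the upper half-width is `r_plus = P84.13 - m` and the lower
#' `r_minus = m - P15.87` (the one-sigma points of a Gaussian). Each
#' protein's outlier score is
#' `z = (x - m) / r_plus` if `x >= m`, else `(m - x) / r_minus`,
#' and its one-sided p-value is the Gaussian upper tail `P(Z > z)`
#' (equivalently `erfc(z / sqrt(2)) / 2`); with `two_sided = TRUE` the
#' p-value is doubled and capped at 1.
#'
#' A trailing bin smaller than `bin_size / 2` is merged into its neighbour;
#' with fewer than `2 * bin_size` proteins a single bin is used. Bins whose
#' ratios are all identical (zero half-width) are merged with a neighbour;
#' if that leaves a single degenerate bin, an error is raised. Percentiles
#' use linear interpolation between order statistics; intensity ties are
#' broken by protein id so the partition is reproducible.
#'
#' @param proteins Output of [compute_protein_ratios()].
#' @param comparison A [comparison()] or its id string; selects the
#'   `log2_<id>` column.
#' @param bin_size Target number of proteins per intensity bin.
#' @param two_sided Double the tail probability.
#' @return A tibble (one row per protein with a defined ratio, input order
#'   preserved): protein_group, summed_intensity, log2_ratio, bin,
#'   bin_median, r_plus, r_minus, z, p_value.
#' @export
significance_b <- function(proteins, comparison, bin_size = 300,
                           two_sided = FALSE) {
  id <- if (inherits(comparison, "comparison")) comparison$id else as.character(comparison)
  col <- paste0("log2_", id)
  if (!col %in% names(proteins)) {
    stop_input(sprintf("no column '%s' in the protein table", col))
  }
  df <- proteins %>%
    select("protein_group", "summed_intensity", log2_ratio = all_of(col)) %>%
    filter(!is.na(.data$log2_ratio), is.finite(.data$log2_ratio))
  n <- nrow(df)
  if (n < 10) stop_input("need at least 10 quantified proteins for Significance B")

  # sort by decreasing abundance, ties broken by protein id
  ord <- order(-df$summed_intensity, df$protein_group)
  df <- df[ord, ]
  bin <- if (n < 2 * bin_size) {
    rep(1L, n)
  } else {
    b <- ceiling(seq_len(n) / bin_size)
    last <- max(b)
    if (sum(b == last) < bin_size / 2) b[b == last] <- last - 1L
    b
  }

  repeat {
    stats_tbl <- bin_ratio_stats(df$log2_ratio, bin)
    degen <- stats_tbl$bin[stats_tbl$r_plus <= 0 | stats_tbl$r_minus <= 0]
    if (length(degen) == 0) break
    if (length(unique(bin)) == 1) {
      stop_input("all log2 ratios identical: the null distribution is degenerate")
    }
    # merge the first degenerate bin into its neighbour and renumber
    b0 <- degen[1]
    target <- if (b0 > min(bin)) max(bin[bin < b0]) else min(bin[bin > b0])
    bin[bin == b0] <- target
    bin <- as.integer(factor(bin))
  }

  stats_tbl <- bin_ratio_stats(df$log2_ratio, bin)
  df$bin <- bin
  df <- df %>% left_join(stats_tbl, by = "bin")
  up <- df$log2_ratio >= df$bin_median
  df$z <- ifelse(up,
    (df$log2_ratio - df$bin_median) / df$r_plus,
    (df$bin_median - df$log2_ratio) / df$r_minus
  )
  df$p_value <- pnorm(df$z, lower.tail = FALSE)
  if (two_sided) df$p_value <- pmin(1, 2 * df$p_value)
  # restore the caller's row order
  df[order(ord), ]
}

bin_ratio_stats <- function(log2_ratio, bin) {
  tibble(log2_ratio = log2_ratio, bin = bin) %>%
    group_by(.data$bin) %>%
    summarise(
      bin_median = median(.data$log2_ratio),
      r_plus = quantile(.data$log2_ratio, 0.8413, names = FALSE) -
        median(.data$log2_ratio),
      r_minus = median(.data$log2_ratio) -
        quantile(.data$log2_ratio, 0.1587, names = FALSE),
      .groups = "drop"
    )
}
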