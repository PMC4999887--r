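#' Technical-replicate concordance QC
#'
#' Summarises how well two channels carrying the same labelled sample agree:
#' the standard deviation of the per-protein log2 intensity ratio (the
#' quantification noise floor, which motivates the fold-change cutoff), the
#' squared Pearson correlation and ordinary-least-squares slope of the two
#' channels' intensities, and the percent-variation distribution
#' `|I_A - I_B| / mean(I_A, I_B) * 100` with its empirical cumulative curve.
#'
#' @param proteins Output of [compute_protein_ratios()] (needs the
#'   per-channel `I114`..`I117` columns).
#' @param replicate_pair A [comparison()] naming the two replicate channels
#'   (channel A = numerator, channel B = denominator); multi-channel sides
#'   are aggregated by geometric mean.
#' @return A `qc_report` object; see [glance.qc_report()] for the scalar
#'   summary and [tidy.qc_report()] for the cumulative variation curve.
#' @export
replicate_qc <- function(proteins, replicate_pair) {
  stopifnot(inherits(replicate_pair, "comparison"))
  a_cols <- paste0("I", replicate_pair$numerator)
  b_cols <- paste0("I", replicate_pair$denominator)
  ia <- exp(rowMeans(log(as.matrix(proteins[a_cols]))))
  ib <- exp(rowMeans(log(as.matrix(proteins[b_cols]))))
  keep <- is.finite(ia) & is.finite(ib) & ia > 0 & ib > 0
  ia <- ia[keep]
  ib <- ib[keep]
  if (length(ia) < 3) stop_input("need at least 3 proteins quantified in both channels")

  if (sd(ia) == 0 || sd(ib) == 0) {
    warn("zero-variance channel: correlation and slope are undefined")
    r2 <- NA_real_
    slope <- NA_real_
    intercept <- NA_real_
  } else {
    r2 <- cor(ia, ib)^2
    fit <- coef(lm(ib ~ ia))
    slope <- unname(fit[2])
    intercept <- unname(fit[1])
  }
  pct <- abs(ia - ib) / ((ia + ib) / 2) * 100
  curve <- tibble(
    pct_variation = sort(pct),
    cum_fraction = seq_along(pct) / length(pct)
  )
  structure(
    list(
      pair = replicate_pair,
      n = length(ia),
      sigma_log2 = sd(log2(ia / ib)),
      pearson_r2 = r2,
      regression_slope = slope,
      regression_intercept = intercept,
      intensity_a = ia,
      intensity_b = ib,
      pct_variation = pct,
      variation_curve = curve
    ),
    class = "qc_report"
  )
}

#' Fraction of proteins within a percent-variation bound
#'
#' @param qc A `qc_report`.
#' @param v Percent-variation threshold (e.g. 30).
#' @return Fraction of proteins with percent variation <= `v`.
#' @export
frac_within <- function(qc, v) {
  stopifnot(inherits(qc, "qc_report"))
  mean(qc$pct_variation <= v)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "Replicate QC (%s vs %s), n = %d proteins\n",
    paste(x$pair$numerator, collapse = "+"),
    paste(x$pair$denominator, collapse = "+"), x$n
  ))
  cat(sprintf("  sigma(log2 ratio):  %.4f\n", x$sigma_log2))
  cat(sprintf("  Pearson R^2:        %.4f\n", x$pearson_r2))
  cat(sprintf("  regression slope:   %.4f\n", x$regression_slope))
  cat(sprintf("  within 30%% variation: %.1f%%\n", 100 * frac_within(x, 30)))
  invisible(x)
}

#' Scalar summary of a replicate-QC report
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return A one-row tibble with n, sigma_log2, pearson_r2,
#'   regression_slope and the fraction of proteins within 30% variation.
#' @exportS3Method generics::glance
glance.qc_report <- function(x, ...) {
  tibble(
    n = x$n,
    sigma_log2 = x$sigma_log2,
    pearson_r2 = x$pearson_r2,
    regression_slope = x$regression_slope,
    frac_within_30 = frac_within(x, 30)
  )
}

#' Cumulative percent-variation curve of a replicate-QC report
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return A tibble with `pct_variation` and the cumulative fraction of
#'   proteins at or below it (non-decreasing, ending at 1).
#' @exportS3Method generics::tidy
tidy.qc_report <- function(x, ...) {
  x$variation_curve
}

#' Check that the four channels were mixed in equal amounts
#'
#' Equal total peptide input per channel should put the median log2 ratio of
#' every channel against the reference near zero. Reports median and
#' quartiles of `log2(channel / reference)` over proteins and flags channels
#' whose |median| exceeds `tolerance`.
#'
#' @param proteins Output of [compute_protein_ratios()].
#' @param reference_channel Reference channel label (default "114").
#' @param tolerance Flagging threshold on the |median log2 ratio|.
#' @return A tibble with one row per non-reference channel.
#' @export
mixing_check <- function(proteins, reference_channel = "114", tolerance = 0.5) {
  reference_channel <- as.character(reference_channel)
  if (!reference_channel %in% ITRAQ_CHANNELS) {
    stop_input("`reference_channel` must be one of 114/115/116/117")
  }
  ref <- proteins[[paste0("I", reference_channel)]]
  purrr::map_dfr(setdiff(ITRAQ_CHANNELS, reference_channel), function(ch) {
    x <- proteins[[paste0("I", ch)]]
    ok <- x > 0 & ref > 0
    lr <- log2(x[ok] / ref[ok])
    tibble(
      channel = ch,
      reference = reference_channel,
      n = sum(ok),
      median_log2 = median(lr),
      q25 = quantile(lr, 0.25, names = FALSE),
      q75 = quantile(lr, 0.75, names = FALSE),
      flagged = abs(median(lr)) > tolerance
    )
  })
}

#' Centre a comparison's ratios on a median of zero
#'
#' Shifts all log2 ratios of one comparison so their median is exactly zero
#' (and rescales the ratio column accordingly). The equal-mixing design makes
#' this unnecessary when [mixing_check()] passes, so it is opt-in rather
#' than part of the default pipeline.
#'
#' @param proteins Output of [compute_protein_ratios()].
#' @param comparison A [comparison()] or id string.
#' @return The protein table with adjusted `ratio_<id>` and `log2_<id>`.
#' @export
median_normalize <- function(proteins, comparison) {
  id <- if (inherits(comparison, "comparison")) comparison$id else as.character(comparison)
  lcol <- paste0("log2_", id)
  rcol <- paste0("ratio_", id)
  if (!lcol %in% names(proteins)) {
    stop_input(sprintf("no column '%s' in the protein table", lcol))
  }
  shift <- median(proteins[[lcol]], na.rm = TRUE)
  proteins[[lcol]] <- proteins[[lcol]] - shift
  proteins[[rcol]] <- 2^proteins[[lcol]]
  proteins
}
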