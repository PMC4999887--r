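#' Filter PSMs on identification confidence and reporter completeness
#'
#' Mirrors the two identification-level gates applied before quantification:
#' a PSM is kept only if its confidence score (an FDR/posterior-error-style
#' quantity, lower is better) does not exceed `min_confidence`, and — when
#' `require_complete` — only if all four reporter channels carry strictly
#' positive intensity, since a missing reporter makes every ratio involving
#' that channel undefined.
#'
#' @param psms A PSM tibble (see [read_psm_table()]).
#' @param min_confidence Maximum accepted confidence score (default 0.01,
#'   i.e. a 1% identification FDR).
#' @param require_complete Drop PSMs with any zero/absent reporter intensity.
#' @param quiet Suppress the per-reason removal message.
#' @return The retained rows, with a `filter_counts` attribute holding the
#'   number removed per reason (low-confidence counted first, completeness
#'   among the survivors).
#' @export
filter_psms <- function(psms, min_confidence = 0.01, require_complete = TRUE,
                        quiet = FALSE) {
  psms <- validate_psm_table(psms)
  conf_ok <- psms$confidence <= min_confidence
  intens <- as.matrix(psms[intensity_cols()])
  complete <- rowSums(intens > 0) == 4L
  keep <- conf_ok & (!require_complete | complete)

  counts <- c(
    low_confidence = sum(!conf_ok),
    incomplete_reporter = if (require_complete) sum(conf_ok & !complete) else 0L
  )
  if (!quiet) {
    message(sprintf(
      "filter_psms: %d/%d PSMs retained (%d low-confidence, %d incomplete reporter removed)",
      sum(keep), nrow(psms), counts[["low_confidence"]],
      counts[["incomplete_reporter"]]
    ))
  }
  out <- psms[keep, , drop = FALSE]
  attr(out, "filter_counts") <- counts
  out
}

#' Correct reporter intensities for isotope impurities
#'
#' Each tag's reagent carries isotopic impurities that deposit a known
#' fraction of its signal into neighbouring channels. With mixing matrix `M`
#' (entry (i, j) = fraction of tag j observed in channel i) the observed
#' intensity vector per PSM is `M %*% x`; this function recovers `x` by
#' solving the 4x4 linear system for every row. Components driven slightly
#' negative by noise are clamped to zero with a warning reporting the count.
#' The identity matrix is an exact no-op.
#'
#' @param psms A PSM tibble.
#' @param matrix A [correction_matrix()].
#' @return The tibble with corrected `I114`..`I117`.
#' @export
correct_isotope_impurities <- function(psms, matrix) {
  matrix <- correction_matrix(matrix)
  psms <- validate_psm_table(psms)
  if (nrow(psms) == 0) return(psms)
  observed <- as.matrix(psms[intensity_cols()])
  corrected <- t(solve(unclass(matrix), t(observed)))
  n_neg <- sum(corrected < 0)
  if (n_neg > 0) {
    warn(sprintf(
      "isotope correction produced %d negative intensities; clamped to 0", n_neg
    ))
    corrected[corrected < 0] <- 0
  }
  psms[intensity_cols()] <- as.data.frame(corrected)
  psms
}

#' Roll PSMs up to peptide-level intensities
#'
#' Peptide intensities are the arithmetic mean, per channel, over all
#' retained PSMs of that peptide (one row per peptide/protein-group pair).
#'
#' @param psms A filtered, corrected PSM tibble.
#' @return A tibble with peptide, protein_group, is_unique, n_psms and
#'   per-channel mean intensities.
#' @export
rollup_peptides <- function(psms) {
  psms <- validate_psm_table(psms)
  psms %>%
    group_by(.data$peptide, .data$protein_group, .data$is_unique) %>%
    summarise(
      n_psms = dplyr::n(),
      across(all_of(intensity_cols()), mean),
      .groups = "drop"
    )
}

#' Define a channel comparison
#'
#' A comparison divides the (geometric-mean) intensity of its numerator
#' channels by that of its denominator channels. Channel sets must be
#' disjoint subsets of 114/115/116/117.
#'
#' @param id Short identifier used in column names (`ratio_<id>`).
#' @param numerator,denominator Character vectors of channel labels.
#' @return A `comparison` object.
#' @export
#' @examples
#' comparison("MIIG_vs_GVO", "116", c("114", "115"))
comparison <- function(id, numerator, denominator) {
  numerator <- as.character(numerator)
  denominator <- as.character(denominator)
  if (length(numerator) == 0 || length(denominator) == 0) {
    stop_input("both sides of a comparison need at least one channel")
  }
  bad <- setdiff(c(numerator, denominator), ITRAQ_CHANNELS)
  if (length(bad) > 0) {
    stop_input(sprintf("unknown channel(s): %s", paste(bad, collapse = ", ")))
  }
  if (length(intersect(numerator, denominator)) > 0) {
    stop_input("numerator and denominator channels must be disjoint")
  }
  structure(
    list(id = as.character(id), numerator = numerator, denominator = denominator),
    class = "comparison"
  )
}

#' The two contrasts of the pooled-reference oocyte design
#'
#' Competent matured oocytes (tag 116) against the pooled immature sample
#' (tags 114 and 115), and against incompetent matured oocytes (tag 117).
#' The competent-MII channel is the numerator in both.
#'
#' @return A named list of two [comparison()] objects.
#' @export
default_comparisons <- function() {
  list(
    MIIG_vs_GVO = comparison("MIIG_vs_GVO", "116", c("114", "115")),
    MIIG_vs_MIIB = comparison("MIIG_vs_MIIB", "116", "117")
  )
}

as_comparison_list <- function(comparisons) {
  if (inherits(comparisons, "comparison")) comparisons <- list(comparisons)
  if (!all(vapply(comparisons, inherits, logical(1), "comparison"))) {
    stop_input("`comparisons` must be comparison objects; see comparison()")
  }
  setNames(comparisons, vapply(comparisons, `[[`, character(1), "id"))
}

#' Protein-level quantification from peptide intensities
#'
#' For each protein group and comparison, every usable unique peptide
#' contributes the ratio of the geometric mean of its numerator-channel
#' intensities to that of its denominator channels, and the protein ratio is
#' the geometric mean of those unique-peptide ratios. A peptide is usable
#' for a comparison only if all channels on both sides are strictly
#' positive; excluded peptides are counted and reported. Proteins with fewer
#' than `min_unique_for_quant` usable unique peptides get `NA` for that
#' comparison. Non-unique (shared) peptides never contribute to any ratio.
#'
#' Per-channel protein intensities (`I114`..`I117`, summed over unique
#' peptides) are retained for replicate QC, and `summed_intensity` — their
#' total across channels — is the abundance proxy used for Significance-B
#' binning.
#'
#' @param peptides Output of [rollup_peptides()].
#' @param comparisons A [comparison()] or list of them.
#' @param min_unique_for_quant Minimum usable unique peptides for a ratio
#'   (default 1).
#' @param quiet Suppress the excluded-peptide message.
#' @return A tibble with one row per protein group: peptide counts, channel
#'   intensities, `summed_intensity`, and `ratio_<id>` / `log2_<id>` per
#'   comparison.
#' @export
compute_protein_ratios <- function(peptides, comparisons,
                                   min_unique_for_quant = 1, quiet = FALSE) {
  comparisons <- as_comparison_list(comparisons)
  if (nrow(peptides) == 0) stop_input("peptide table is empty")

  proteins <- peptides %>%
    group_by(.data$protein_group) %>%
    summarise(
      n_peptides = n_distinct(.data$peptide),
      n_unique_peptides = n_distinct(.data$peptide[.data$is_unique]),
      n_psms = sum(.data$n_psms),
      .groups = "drop"
    )

  uniq <- peptides %>% filter(.data$is_unique)
  channel_sums <- uniq %>%
    group_by(.data$protein_group) %>%
    summarise(across(all_of(intensity_cols()), sum), .groups = "drop")
  proteins <- proteins %>%
    left_join(channel_sums, by = "protein_group") %>%
    mutate(
      across(all_of(intensity_cols()), function(x) dplyr::coalesce(x, 0)),
      summed_intensity = rowSums(dplyr::pick(all_of(intensity_cols())))
    )
  for (cmp in comparisons) {
    num <- as.matrix(uniq[paste0("I", cmp$numerator)])
    den <- as.matrix(uniq[paste0("I", cmp$denominator)])
    usable <- rowSums(num > 0) == ncol(num) & rowSums(den > 0) == ncol(den)
    n_excluded <- sum(!usable)
    if (n_excluded > 0 && !quiet) {
      message(sprintf(
        "compute_protein_ratios [%s]: %d unique peptide(s) excluded for zero intensities",
        cmp$id, n_excluded
      ))
    }
    pep_ratio <- exp(rowMeans(log(num)) - rowMeans(log(den)))
    ratios <- uniq %>%
      mutate(.usable = usable, .ratio = pep_ratio) %>%
      filter(.data$.usable) %>%
      group_by(.data$protein_group) %>%
      summarise(
        .n_used = dplyr::n(),
        .protein_ratio = geomean(.data$.ratio),
        .groups = "drop"
      ) %>%
      filter(.data$.n_used >= min_unique_for_quant)
    proteins[[paste0("ratio_", cmp$id)]] <-
      ratios$.protein_ratio[match(proteins$protein_group, ratios$protein_group)]
    proteins[[paste0("log2_", cmp$id)]] <- log2(proteins[[paste0("ratio_", cmp$id)]])
  }
  proteins %>% arrange(.data$protein_group)
}
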