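#' Call differentially expressed proteins for one comparison
#'
#' A protein is up-regulated when its ratio is at least `fc_up`, down when
#' at most `fc_down`, and in either case only if its outlier p-value is
#' below `alpha` and it carries at least `min_unique` unique peptides.
#' Defaults are the conventional cutoffs for this noise floor: 2-fold
#' change (both bounds inclusive), p < 0.05, and two unique peptides.
#' Proteins lacking a ratio or p-value are `not_tested`.
#'
#' @param proteins Output of [compute_protein_ratios()].
#' @param significance Matching [significance_b()] table for the same
#'   comparison.
#' @param comparison A [comparison()] or id string.
#' @param fc_up,fc_down Fold-change bounds (inclusive); `fc_up` must exceed
#'   `fc_down`.
#' @param alpha P-value threshold (strict).
#' @param min_unique Minimum unique peptides for a DE call.
#' @return A tibble of DE calls: protein_group, comparison, ratio,
#'   log2_ratio, p_value, n_unique_peptides,
#'   status in up/down/ns/not_tested.
#' @export
call_differential <- function(proteins, significance, comparison,
                              fc_up = 2, fc_down = 0.5, alpha = 0.05,
                              min_unique = 2) {
  if (fc_up <= fc_down) stop_input("`fc_up` must be greater than `fc_down`")
  id <- if (inherits(comparison, "comparison")) comparison$id else as.character(comparison)
  rcol <- paste0("ratio_", id)
  if (!rcol %in% names(proteins)) {
    stop_input(sprintf("no column '%s' in the protein table", rcol))
  }
  calls <- proteins %>%
    select("protein_group", "n_unique_peptides",
      ratio = all_of(rcol), log2_ratio = all_of(paste0("log2_", id))
    ) %>%
    left_join(
      significance %>% select("protein_group", "p_value"),
      by = "protein_group"
    ) %>%
    mutate(
      comparison = id,
      status = case_when(
        is.na(.data$ratio) | is.na(.data$p_value) ~ "not_tested",
        .data$ratio >= fc_up & .data$p_value < alpha &
          .data$n_unique_peptides >= min_unique ~ "up",
        .data$ratio <= fc_down & .data$p_value < alpha &
          .data$n_unique_peptides >= min_unique ~ "down",
        TRUE ~ "ns"
      )
    ) %>%
    select(
      "protein_group", "comparison", "ratio", "log2_ratio", "p_value",
      "n_unique_peptides", "status"
    )
  calls
}

#' Per-comparison counts of DE calls
#'
#' @param de_calls One or more [call_differential()] tables bound together.
#' @return A tibble with comparison, n_up, n_down and n_total
#'   (= n_up + n_down).
#' @export
de_summary <- function(de_calls) {
  de_calls %>%
    group_by(.data$comparison) %>%
    summarise(
      n_up = sum(.data$status == "up"),
      n_down = sum(.data$status == "down"),
      n_tested = sum(.data$status != "not_tested"),
      .groups = "drop"
    ) %>%
    mutate(n_total = .data$n_up + .data$n_down)
}

#' Log2-ratio profiles of the DE union
#'
#' Builds the clustering input: one row per protein called up or down in at
#' least one comparison, one log2-ratio column per comparison. A protein
#' unquantified in some comparison gets `NA` there (imputed as 0 and
#' flagged by [cluster_profiles()]).
#'
#' @param de_calls Bound [call_differential()] tables over all comparisons.
#' @return A tibble: protein_group plus one `log2_<comparison>` column each.
#' @export
de_profiles <- function(de_calls) {
  union_ids <- de_calls %>%
    filter(.data$status %in% c("up", "down")) %>%
    distinct(.data$protein_group)
  de_calls %>%
    dplyr::semi_join(union_ids, by = "protein_group") %>%
    select("protein_group", "comparison", "log2_ratio") %>%
    tidyr::pivot_wider(
      names_from = "comparison", values_from = "log2_ratio",
      names_prefix = "log2_"
    ) %>%
    arrange(.data$protein_group)
}
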