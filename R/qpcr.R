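#' Read a qPCR Ct table
#'
#' Expects a TSV with columns `gene`, `sample_group`, `replicate` and `ct`
#' (threshold cycle, positive).
#'
#' @param path Path to the TSV file.
#' @return A validated tibble.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("Ct file not found: '%s'", path))
  ct <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    sample_group = readr::col_character(),
    replicate = readr::col_integer(),
    ct = readr::col_double()
  ))
  validate_ct_table(ct)
}

validate_ct_table <- function(ct) {
  required <- c("gene", "sample_group", "replicate", "ct")
  missing <- setdiff(required, names(ct))
  if (length(missing) > 0) {
    stop_input(sprintf(
      "Ct table is missing column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  if (any(is.na(ct$ct) | ct$ct <= 0)) stop_input("all Ct values must be > 0")
  as_tibble(ct[required])
}

#' Relative expression by the 2^-ddCt (Livak) method
#'
#' Per gene and sample group, the mean Ct is normalized to the reference
#' gene of the same group (`dCt = mean(Ct_target) - mean(Ct_reference)`),
#' then to the calibrator group (`ddCt = dCt_group - dCt_calibrator`), and
#' relative quantity is `RQ = 2^-ddCt`, assuming perfect doubling per
#' cycle. The calibrator group's RQ is exactly 1 by construction. Replicate
#' dCt values (each replicate's Ct minus the group's mean reference Ct) are
#' retained for dispersion and for [compare_groups()].
#'
#' @param ct A Ct tibble (see [read_ct_table()]).
#' @param reference_gene Housekeeping gene used for normalization; must be
#'   measured in every group.
#' @param calibrator_group Group whose expression defines RQ = 1.
#' @return A tibble per target gene x group: n_replicates, delta_ct,
#'   sd_delta_ct, delta_delta_ct, rq; replicate-level dCt/RQ values are in
#'   the `replicates` attribute.
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   gene = rep(c("ACTB", "BMP15"), each = 2),
#'   sample_group = rep(c("GVO", "MII_G"), 2),
#'   replicate = 1L,
#'   ct = c(20, 21, 25, 24)
#' )
#' delta_delta_ct(ct, reference_gene = "ACTB", calibrator_group = "GVO")
delta_delta_ct <- function(ct, reference_gene, calibrator_group) {
  ct <- validate_ct_table(ct)
  groups <- unique(ct$sample_group)
  if (!calibrator_group %in% groups) {
    stop_input(sprintf("calibrator group '%s' not present", calibrator_group))
  }
  ref <- ct %>%
    filter(.data$gene == reference_gene) %>%
    group_by(.data$sample_group) %>%
    summarise(ref_ct = mean(.data$ct), .groups = "drop")
  missing_ref <- setdiff(groups, ref$sample_group)
  if (length(missing_ref) > 0) {
    stop_input(sprintf(
      "reference gene '%s' is missing in group(s): %s",
      reference_gene, paste(missing_ref, collapse = ", ")
    ))
  }

  reps <- ct %>%
    filter(.data$gene != reference_gene) %>%
    left_join(ref, by = "sample_group") %>%
    mutate(delta_ct = .data$ct - .data$ref_ct)

  dct <- reps %>%
    group_by(.data$gene, .data$sample_group) %>%
    summarise(
      n_replicates = dplyr::n(),
      delta_ct = mean(.data$delta_ct),
      sd_delta_ct = sd(.data$delta_ct),
      .groups = "drop"
    )
  calib <- dct %>%
    filter(.data$sample_group == calibrator_group) %>%
    select("gene", calibrator_delta_ct = "delta_ct")
  out <- dct %>%
    left_join(calib, by = "gene") %>%
    mutate(
      delta_delta_ct = .data$delta_ct - .data$calibrator_delta_ct,
      rq = 2^(-.data$delta_delta_ct)
    ) %>%
    select(
      "gene", "sample_group", "n_replicates", "delta_ct", "sd_delta_ct",
      "delta_delta_ct", "rq"
    ) %>%
    arrange(.data$gene, .data$sample_group)

  rep_out <- reps %>%
    left_join(calib, by = "gene") %>%
    mutate(rq = 2^(-(.data$delta_ct - .data$calibrator_delta_ct))) %>%
    select("gene", "sample_group", "replicate", "delta_ct", "rq")
  attr(out, "replicates") <- rep_out
  out
}

#' Replicate-level dCt values of a relative-quantification result
#'
#' @param rq Output of [delta_delta_ct()].
#' @return Tibble with gene, sample_group, replicate, delta_ct, rq.
#' @export
rq_replicates <- function(rq) {
  reps <- attr(rq, "replicates")
  if (is.null(reps)) stop_input("`rq` carries no replicate-level values")
  reps
}

#' Two-group comparison of qPCR expression
#'
#' Welch's two-sample t-test on the replicate dCt values of one gene in two
#' sample groups (the scale on which qPCR noise is approximately normal).
#' When both groups have zero variance the test statistic is defined by
#' continuity: 0 with p = 1 for equal means, infinite with p = 0 otherwise.
#'
#' @param rq Output of [delta_delta_ct()].
#' @param gene Target gene.
#' @param group_a,group_b Sample groups to compare.
#' @param alpha Significance threshold for the flag.
#' @return One-row tibble: gene, group_a, group_b, statistic, df, p_value,
#'   significant.
#' @export
compare_groups <- function(rq, gene, group_a, group_b, alpha = 0.05) {
  reps <- rq_replicates(rq)
  a <- reps %>% filter(.data$gene == !!gene, .data$sample_group == group_a) %>% pull("delta_ct")
  b <- reps %>% filter(.data$gene == !!gene, .data$sample_group == group_b) %>% pull("delta_ct")
  if (length(a) < 2 || length(b) < 2) {
    stop_input("need at least 2 replicates per group")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    stat <- if (equal) 0 else Inf
    p <- if (equal) 1 else 0
    df <- NA_real_
  } else {
    tt <- t.test(a, b, var.equal = FALSE)
    stat <- unname(tt$statistic)
    p <- tt$p.value
    df <- unname(tt$parameter)
  }
  tibble(
    gene = gene, group_a = group_a, group_b = group_b,
    statistic = stat, df = df, p_value = p,
    significant = p < alpha
  )
}
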