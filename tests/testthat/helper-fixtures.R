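# Small in-code fixtures shared across tests.

# a minimal valid PSM tibble; intensities given per channel as a 4-col matrix
make_psms <- function(intensities, peptide = NULL, protein = NULL,
                      is_unique = TRUE, confidence = 0.001) {
  intensities <- matrix(intensities, ncol = 4, byrow = TRUE)
  n <- nrow(intensities)
  out <- tibble::tibble(
    spectrum_id = sprintf("s%03d", seq_len(n)),
    peptide = peptide %||% sprintf("pep%03d", seq_len(n)),
    protein_group = protein %||% "P1",
    is_unique = is_unique,
    confidence = confidence
  )
  colnames(intensities) <- paste0("I", c(114, 115, 116, 117))
  cbind(out, tibble::as_tibble(intensities))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# noise-free generator settings: identity mixing, no decoys, no shared peptides
noise_free_config <- function(n_proteins = 40, seed = 11, ...) {
  args <- utils::modifyList(
    list(
      n_proteins = n_proteins, tech_noise_sd = 0, frac_low_confidence = 0,
      frac_shared_peptides = 0, seed = seed
    ),
    list(...)
  )
  do.call(sim_config, args)
}

quantify_sim <- function(cfg, comparisons = default_comparisons(),
                         matrix = NULL) {
  truth <- generate_ground_truth(cfg)
  psms <- simulate_psm_table(truth, cfg)
  filtered <- suppressMessages(filter_psms(psms))
  if (!is.null(matrix)) filtered <- correct_isotope_impurities(filtered, matrix)
  peptides <- rollup_peptides(filtered)
  proteins <- suppressMessages(compute_protein_ratios(peptides, comparisons))
  list(truth = truth, psms = psms, proteins = proteins)
}

# true ratio of channel multipliers for a comparison, per protein
true_ratios <- function(truth, cmp) {
  m <- as.matrix(truth$proteins[paste0("mult_", c(114, 115, 116, 117))])
  colnames(m) <- c("114", "115", "116", "117")
  num <- exp(rowMeans(log(m[, cmp$numerator, drop = FALSE])))
  den <- exp(rowMeans(log(m[, cmp$denominator, drop = FALSE])))
  stats::setNames(num / den, truth$proteins$protein_group)
}
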