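#' Draw the ground truth for a simulated 4-plex experiment
#'
#' Assigns every protein a base intensity and per-channel abundance
#' multipliers. Exactly `round(frac_de * n_proteins)` proteins are
#' differential: half up, half down (extra one up), with the fold change
#' applied to `de_channel`. Channels 114 and 115 carry the same biological
#' sample, so their multipliers are always equal; null proteins have all four
#' multipliers equal to 1. Peptides are then laid out per protein with
#' per-peptide ionization efficiencies and optional sharing between proteins.
#'
#' Deterministic given `config$seed`; the caller's RNG state is untouched.
#'
#' @param config A [sim_config()].
#' @return A `ground_truth` list with tibbles `proteins` (protein_group,
#'   base_log2_intensity, mult_114..mult_117, is_de, direction) and
#'   `peptides` (peptide, protein_group, parents, is_unique,
#'   log2_efficiency), plus the config.
#' @export
generate_ground_truth <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    n <- config$n_proteins
    ids <- sprintf("PROT%04d", seq_len(max(n, 1))[seq_len(n)])
    base <- rnorm(n, config$base_log2_intensity_mean, config$base_log2_intensity_sd)

    n_de <- round(config$frac_de * n)
    de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer()
    direction <- rep("null", n)
    if (n_de > 0) {
      dirs <- rep(c("up", "down"), length.out = n_de)
      direction[de_idx] <- sample(dirs) # random assignment of balanced signs
    }

    mult <- matrix(1, nrow = n, ncol = 4, dimnames = list(NULL, ITRAQ_CHANNELS))
    fc <- 2^config$log2fc_magnitude
    mult[direction == "up", config$de_channel] <- fc
    mult[direction == "down", config$de_channel] <- 1 / fc

    proteins <- tibble(
      protein_group = ids,
      base_log2_intensity = base,
      mult_114 = mult[, "114"], mult_115 = mult[, "115"],
      mult_116 = mult[, "116"], mult_117 = mult[, "117"],
      is_de = direction != "null",
      direction = direction
    )

    n_pep <- draw_counts(n, config$peptides_per_protein_dist)
    peptides <- tibble(
      peptide = as.character(unlist(purrr::map2(ids, n_pep, function(id, k) {
        sprintf("%s_pep%02d", id, seq_len(k))
      }), use.names = FALSE)),
      parent1 = rep(ids, n_pep)
    )
    n_total <- nrow(peptides)
    shared <- rep(FALSE, n_total)
    parent2 <- rep(NA_character_, n_total)
    if (config$frac_shared_peptides > 0 && n > 1) {
      k_shared <- round(config$frac_shared_peptides * n_total)
      if (k_shared > 0) {
        sh_idx <- sample.int(n_total, k_shared)
        shared[sh_idx] <- TRUE
        # second parent: any protein other than the first
        parent2[sh_idx] <- purrr::map_chr(peptides$parent1[sh_idx], function(p1) {
          sample(setdiff(ids, p1), 1L)
        })
      }
    }
    peptides <- peptides %>%
      mutate(
        parents = ifelse(shared, paste(.data$parent1, parent2, sep = ";"),
                         .data$parent1),
        protein_group = .data$parents,
        is_unique = !shared,
        log2_efficiency = rnorm(n_total, 0, config$peptide_efficiency_sd)
      ) %>%
      select("peptide", "protein_group", "parents", "is_unique", "log2_efficiency")

    structure(
      list(proteins = proteins, peptides = peptides, config = config),
      class = "ground_truth"
    )
  })
}

#' Simulate a PSM table from a ground truth
#'
#' Forward model for one 4-plex LC-MS/MS run. Each peptide's true channel
#' intensity is the sum over its parent proteins of
#' `2^base_log2_intensity * multiplier(channel) * 2^log2_efficiency`.
#' Every PSM observes those four values under independent multiplicative
#' lognormal noise (sd `tech_noise_sd` on the log2 scale, per channel), then
#' the isotope-impurity matrix mixes the channels:
#' `observed = M %*% (true * noise)`. A fraction of PSMs is assigned a
#' low confidence score to exercise the identification filter; the rest draw
#' confidence uniformly below 0.01.
#'
#' Deterministic given `config$seed` (a stream distinct from the one used by
#' [generate_ground_truth()]).
#'
#' @param truth A `ground_truth` from [generate_ground_truth()] built from
#'   the same config.
#' @param config The [sim_config()] used to build `truth`.
#' @return A tibble of PSM records with columns spectrum_id, peptide,
#'   protein_group, is_unique, confidence, I114, I115, I116, I117.
#' @export
simulate_psm_table <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"))
  validate_sim_config(config)
  M <- unclass(config$impurity_matrix)
  if (!is_invertible(M)) stop_input("impurity matrix is singular or ill-conditioned")

  peptides <- truth$peptides
  if (nrow(peptides) == 0) {
    return(empty_psm_table())
  }

  # true per-peptide channel intensities (sum over parent proteins)
  prot <- truth$proteins
  base_int <- setNames(2^prot$base_log2_intensity, prot$protein_group)
  mults <- as.matrix(prot[paste0("mult_", ITRAQ_CHANNELS)])
  rownames(mults) <- prot$protein_group

  pep_true <- t(vapply(seq_len(nrow(peptides)), function(i) {
    parents <- strsplit(peptides$parents[i], ";", fixed = TRUE)[[1]]
    eff <- 2^peptides$log2_efficiency[i]
    colSums(mults[parents, , drop = FALSE] * base_int[parents]) * eff
  }, numeric(4)))

  withr::with_seed(config$seed + 1L, {
    n_psm <- draw_counts(nrow(peptides), config$psms_per_peptide_dist)
    idx <- rep(seq_len(nrow(peptides)), n_psm)
    total <- length(idx)

    noise <- matrix(2^rnorm(total * 4, 0, config$tech_noise_sd), ncol = 4)
    observed <- (pep_true[idx, , drop = FALSE] * noise) %*% t(M)

    low <- stats::runif(total) < config$frac_low_confidence
    confidence <- ifelse(low,
      stats::runif(total, 0.011, 0.5),
      stats::runif(total, 0, 0.01)
    )

    out <- tibble(
      spectrum_id = sprintf("scan%06d", seq_len(total)),
      peptide = peptides$peptide[idx],
      protein_group = peptides$protein_group[idx],
      is_unique = peptides$is_unique[idx],
      confidence = confidence
    )
    out[intensity_cols()] <- as.data.frame(observed)
    out
  })
}

empty_psm_table <- function() {
  out <- tibble(
    spectrum_id = character(), peptide = character(),
    protein_group = character(), is_unique = logical(),
    confidence = numeric()
  )
  out[intensity_cols()] <- list(numeric())
  out
}

#' Write a simulated experiment to disk as plain-text fixtures
#'
#' Writes `psms.tsv` (readable by [read_psm_table()]), `truth_proteins.tsv`,
#' `truth_peptides.tsv` and a JSON echo of the configuration. Numeric
#' columns round-trip bit-identically through the package readers.
#'
#' @param truth A `ground_truth`.
#' @param psm_table The matching PSM tibble.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture <- function(truth, psm_table, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_input(sprintf("cannot create directory '%s'", dir))
  }
  paths <- c(
    psms = file.path(dir, "psms.tsv"),
    truth_proteins = file.path(dir, "truth_proteins.tsv"),
    truth_peptides = file.path(dir, "truth_peptides.tsv"),
    config = file.path(dir, "sim_config.json")
  )
  readr::write_tsv(psm_table, paths["psms"])
  readr::write_tsv(truth$proteins, paths["truth_proteins"])
  readr::write_tsv(truth$peptides, paths["truth_peptides"])
  cfg <- unclass(truth$config)
  cfg$impurity_matrix <- matrix(as.numeric(cfg$impurity_matrix), 4, 4)
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
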