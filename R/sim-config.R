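#' Configuration for the synthetic PSM-table generator
#'
#' Describes a 4-plex experiment with two pooled channels for the reference
#' biological sample (tags 114 and 115 carry the same immature-oocyte sample,
#' so their true abundance multipliers are always equal) and one channel each
#' for the two matured samples. Defaults emulate the dataset the package
#' models: the peptide-count-per-protein shape is 17/11/7/6/5/54% for
#' 1/2/3/4/5/6+ unique peptides, differential proteins carry a 4-fold
#' (|log2 FC| = 2) abundance change, and per-PSM reporter noise is lognormal.
#'
#' @param n_proteins Number of proteins to simulate.
#' @param peptides_per_protein_dist Named probability vector over peptide
#'   counts; names are counts ("1", "2", ...) with an optional final "N+"
#'   open category (drawn uniformly from N..N+6). Must sum to 1.
#' @param psms_per_peptide_dist Named probability vector over PSM counts per
#'   peptide, same naming convention.
#' @param base_log2_intensity_mean,base_log2_intensity_sd Mean and sd of the
#'   per-protein base reporter intensity on the log2 scale (arbitrary units).
#' @param peptide_efficiency_sd Sd (log2) of the per-peptide ionization
#'   efficiency factor. It multiplies all four channels of a peptide equally,
#'   so it cancels in every ratio.
#' @param frac_de Fraction of proteins carrying a true fold change; exactly
#'   `round(frac_de * n_proteins)` proteins are differential.
#' @param log2fc_magnitude True |log2 fold change| for differential proteins
#'   (point mass; the 4-fold default matches the fold-change cutoff study).
#' @param de_channel Channel whose sample carries the fold change (default
#'   "116", the competent-MII channel); direction is split 50/50 up/down.
#' @param tech_noise_sd Sd (log2) of independent per-PSM, per-channel
#'   measurement noise.
#' @param frac_shared_peptides Fraction of peptides shared with a second,
#'   randomly chosen protein; shared peptides report the summed signal of
#'   both parents and are flagged non-unique.
#' @param frac_low_confidence Fraction of PSMs given a confidence score above
#'   the default 0.01 identification filter (decoy-like rows exercised by
#'   [filter_psms()]).
#' @param impurity_matrix A [correction_matrix()] applied forward to every
#'   PSM's true channel intensities (isotope cross-talk); identity by default.
#' @param channel_design Named character vector mapping channel to sample
#'   label.
#' @param seed Integer seed; the generator is fully deterministic given it.
#'
#' @return A `sim_config` list, validated.
#' @seealso [generate_ground_truth()], [simulate_psm_table()]
#' @export
#' @examples
#' cfg <- sim_config(n_proteins = 50, seed = 1)
#' truth <- generate_ground_truth(cfg)
#' psms <- simulate_psm_table(truth, cfg)
sim_config <- function(n_proteins = 1000,
                       peptides_per_protein_dist = c(
                         "1" = 0.17, "2" = 0.11, "3" = 0.07,
                         "4" = 0.06, "5" = 0.05, "6+" = 0.54
                       ),
                       psms_per_peptide_dist = c("1" = 0.5, "2" = 0.3, "3" = 0.2),
                       base_log2_intensity_mean = 16,
                       base_log2_intensity_sd = 2,
                       peptide_efficiency_sd = 1,
                       frac_de = 0.1,
                       log2fc_magnitude = 2,
                       de_channel = "116",
                       tech_noise_sd = 0.2,
                       frac_shared_peptides = 0,
                       frac_low_confidence = 0.05,
                       impurity_matrix = NULL,
                       channel_design = c(
                         "114" = "GVO", "115" = "GVO",
                         "116" = "MII_G", "117" = "MII_B"
                       ),
                       seed = 1L) {
  if (is.null(impurity_matrix)) {
    impurity_matrix <- correction_matrix(diag(4))
  } else {
    impurity_matrix <- correction_matrix(impurity_matrix)
  }
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    peptides_per_protein_dist = peptides_per_protein_dist,
    psms_per_peptide_dist = psms_per_peptide_dist,
    base_log2_intensity_mean = base_log2_intensity_mean,
    base_log2_intensity_sd = base_log2_intensity_sd,
    peptide_efficiency_sd = peptide_efficiency_sd,
    frac_de = frac_de,
    log2fc_magnitude = log2fc_magnitude,
    de_channel = as.character(de_channel),
    tech_noise_sd = tech_noise_sd,
    frac_shared_peptides = frac_shared_peptides,
    frac_low_confidence = frac_low_confidence,
    impurity_matrix = impurity_matrix,
    channel_design = channel_design,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_proteins < 0) stop_input("`n_proteins` must be >= 0")
  for (nm in c("frac_de", "frac_shared_peptides", "frac_low_confidence")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop_input(sprintf("`%s` must be in [0, 1]", nm))
    }
  }
  if (cfg$tech_noise_sd < 0) stop_input("`tech_noise_sd` must be >= 0")
  for (nm in c("peptides_per_protein_dist", "psms_per_peptide_dist")) {
    d <- cfg[[nm]]
    if (is.null(names(d)) || any(d < 0) || abs(sum(d) - 1) > 1e-9) {
      stop_input(sprintf(
        "`%s` must be a named non-negative vector summing to 1 (off by %.3g)",
        nm, abs(sum(d) - 1)
      ))
    }
  }
  if (!cfg$de_channel %in% ITRAQ_CHANNELS) {
    stop_input("`de_channel` must be one of 114/115/116/117")
  }
  if (!setequal(names(cfg$channel_design), ITRAQ_CHANNELS)) {
    stop_input("`channel_design` must name all four channels 114-117")
  }
  invisible(cfg)
}

# draw counts from a named categorical distribution; a trailing "N+" category
# is resolved uniformly over N..N+6
draw_counts <- function(n, dist) {
  if (n == 0) return(integer())
  cats <- names(dist)
  picked <- sample(cats, n, replace = TRUE, prob = dist)
  open <- grepl("\\+$", picked)
  counts <- integer(n)
  counts[!open] <- as.integer(picked[!open])
  if (any(open)) {
    base <- as.integer(sub("\\+$", "", picked[open]))
    counts[open] <- base + sample.int(7L, sum(open), replace = TRUE) - 1L
  }
  counts
}
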