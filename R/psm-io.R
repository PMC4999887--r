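#' Read a tab-separated PSM table
#'
#' Expects one row per peptide-spectrum match with columns `spectrum_id`,
#' `peptide`, `protein_group`, `is_unique`, `confidence` and the four
#' reporter-intensity columns `I114`, `I115`, `I116`, `I117`. Row order is
#' preserved. Missing columns raise a schema error naming the column;
#' negative or missing intensities raise a validation error naming the row.
#'
#' @param path Path to a TSV file.
#' @return A tibble of validated PSM records.
#' @export
read_psm_table <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("PSM file not found: '%s'", path))
  psms <- readr::read_tsv(path, col_types = readr::cols(
    spectrum_id = readr::col_character(),
    peptide = readr::col_character(),
    protein_group = readr::col_character(),
    is_unique = readr::col_logical(),
    confidence = readr::col_double(),
    .default = readr::col_double()
  ))
  validate_psm_table(psms)
}

validate_psm_table <- function(psms) {
  required <- c(
    "spectrum_id", "peptide", "protein_group", "is_unique",
    "confidence", intensity_cols()
  )
  missing <- setdiff(required, names(psms))
  if (length(missing) > 0) {
    stop_input(sprintf(
      "PSM table is missing required column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  for (col in intensity_cols()) {
    bad <- which(is.na(psms[[col]]) | psms[[col]] < 0)
    if (length(bad) > 0) {
      stop_input(sprintf(
        "negative or missing intensity in column %s at row %d", col, bad[1]
      ))
    }
  }
  if (any(is.na(psms$confidence) | psms$confidence < 0 | psms$confidence > 1)) {
    stop_input("`confidence` must lie in [0, 1]")
  }
  as_tibble(psms[required])
}

is_invertible <- function(m, max_condition = 1e8) {
  k <- tryCatch(kappa(m, exact = TRUE), error = function(e) Inf)
  is.finite(k) && k <= max_condition
}

#' Construct and validate an isotope-impurity correction matrix
#'
#' Entry (i, j) is the fraction of tag j's true reporter signal that appears
#' in observed channel i; channel order is fixed at 114, 115, 116, 117 on
#' both axes. Columns describe where each tag's signal lands, so every
#' column must be non-negative and sum to at most 1 (signal falling outside
#' the four recorded channels is lost). The matrix must be well conditioned
#' so the correction (solving `M x = observed`) is stable.
#'
#' @param m A 4x4 numeric matrix.
#' @param max_condition Condition-number ceiling beyond which the matrix is
#'   rejected as numerically singular.
#' @return A `correction_matrix` (a classed 4x4 matrix with channel dimnames).
#' @export
#' @examples
#' correction_matrix(diag(4))
correction_matrix <- function(m, max_condition = 1e8) {
  m <- unclass(m)
  if (!is.matrix(m) || !all(dim(m) == c(4, 4)) || !is.numeric(m)) {
    stop_input("a correction matrix must be a numeric 4x4 matrix")
  }
  if (any(m < 0)) stop_input("correction matrix entries must be >= 0")
  cs <- colSums(m)
  if (any(cs > 1 + 1e-9)) {
    stop_input(sprintf(
      "correction matrix column sums must be <= 1 (max observed %.6f)", max(cs)
    ))
  }
  if (!is_invertible(m, max_condition)) {
    stop_input("correction matrix is singular or ill-conditioned")
  }
  dimnames(m) <- list(ITRAQ_CHANNELS, ITRAQ_CHANNELS)
  structure(m, class = c("correction_matrix", "matrix"))
}

#' Read a correction matrix from a TSV file
#'
#' The file holds the 4x4 matrix as fractions (not percentages), rows and
#' columns in channel order 114, 115, 116, 117. A header row and a leading
#' channel-label column are both accepted and ignored.
#'
#' @param path Path to the TSV file.
#' @return A validated [correction_matrix()].
#' @export
read_correction_matrix <- function(path) {
  if (!file.exists(path)) {
    stop_input(sprintf("correction matrix file not found: '%s'", path))
  }
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  num <- raw[vapply(raw, is.numeric, logical(1))]
  # a leading channel-label column (114..117) is tolerated and dropped
  if (ncol(num) == 5 && all(num[[1]] == as.numeric(ITRAQ_CHANNELS))) {
    num <- num[-1]
  }
  if (nrow(num) != 4 || ncol(num) != 4) {
    stop_input("correction matrix file must contain a numeric 4x4 block")
  }
  correction_matrix(as.matrix(num))
}

#' Representative iTRAQ 4-plex impurity matrix
#'
#' Built from typical published isotope-impurity percentages for the 4-plex
#' reagents (-2/-1/+1/+2 Da carry-over per tag). These are illustrative
#' defaults for simulation and examples; for real data use the certificate
#' of analysis shipped with the reagent lot via [read_correction_matrix()].
#'
#' @return A [correction_matrix()].
#' @export
itraq4_impurity_matrix <- function() {
  # rows: tag; columns: % of signal at -2, -1, +1, +2 Da
  imp <- rbind(
    "114" = c(0.0, 1.0, 5.9, 0.2),
    "115" = c(0.0, 2.0, 5.6, 0.1),
    "116" = c(0.0, 3.0, 4.5, 0.1),
    "117" = c(0.1, 4.0, 3.5, 0.1)
  ) / 100
  m <- matrix(0, 4, 4, dimnames = list(ITRAQ_CHANNELS, ITRAQ_CHANNELS))
  for (j in 1:4) {
    m[j, j] <- 1 - sum(imp[j, ])
    off <- c(-2, -1, 1, 2)
    for (k in 1:4) {
      i <- j + off[k]
      if (i >= 1 && i <= 4) m[i, j] <- imp[j, k]
    }
  }
  correction_matrix(m)
}
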