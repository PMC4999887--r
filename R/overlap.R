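#' Overlap between two protein sets
#'
#' Summarises the agreement between two identification (or quantification)
#' lists, e.g. the proteins found in each of two biological replicates. The
#' headline percentage is the intersection over the union, rounded half
#' away from zero to a whole percent, matching how such overlaps are
#' reported.
#'
#' @param set_a,set_b Vectors of protein ids (duplicates ignored).
#' @return A one-row tibble: n_a, n_b, n_common, n_union, percent_common.
#' @export
#' @examples
#' overlap_summary(c("P1", "P2", "P3"), c("P2", "P3", "P4"))
overlap_summary <- function(set_a, set_b) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  n_common <- length(intersect(a, b))
  n_union <- length(union(a, b))
  tibble(
    n_a = length(a),
    n_b = length(b),
    n_common = n_common,
    n_union = n_union,
    percent_common = if (n_union == 0) NA_real_ else
      round_half_away(100 * n_common / n_union)
  )
}
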