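#' Hierarchical clustering of expression profiles
#'
#' Groups proteins with similar regulation patterns across comparisons:
#' agglomerative clustering (Ward linkage on Euclidean distances by
#' default, via [stats::hclust()]) of the raw log2-ratio profiles, with the
#' tree cut to exactly `k` clusters. Profiles are not per-row standardized —
#' with only a couple of comparison dimensions, row z-scoring degenerates.
#' Missing profile entries are imputed as log2 ratio 0 (no change) and
#' flagged. Cluster labels are renumbered 1..k by decreasing size, ties
#' broken by the smallest member id, so labels do not depend on input row
#' order.
#'
#' @param profiles A tibble from [de_profiles()]: protein_group plus
#'   numeric profile columns.
#' @param k Number of clusters.
#' @param linkage Agglomeration method for [stats::hclust()] ("ward.D2" is
#'   Ward's criterion on Euclidean distances).
#' @param metric Distance metric for [stats::dist()].
#' @return A `profile_clusters` object; `tidy()` returns the assignments,
#'   `glance()` the cluster sizes.
#' @export
cluster_profiles <- function(profiles, k = 5, linkage = "ward.D2",
                             metric = "euclidean") {
  value_cols <- setdiff(names(profiles), "protein_group")
  if (length(value_cols) == 0) stop_input("profiles need at least one ratio column")
  if (nrow(profiles) < k) {
    stop_input(sprintf(
      "only %d proteins but k = %d clusters requested; choose a smaller k",
      nrow(profiles), k
    ))
  }
  if (k < 1) stop_input("`k` must be >= 1")

  m <- as.matrix(profiles[value_cols])
  rownames(m) <- profiles$protein_group
  imputed <- setNames(rowSums(is.na(m)) > 0, rownames(m))
  m[is.na(m)] <- 0

  # order rows by id so tie-breaks in the dendrogram are reproducible
  ord <- order(rownames(m))
  m <- m[ord, , drop = FALSE]
  tree <- hclust(dist(m, method = metric), method = linkage)
  raw <- cutree(tree, k = k)

  # renumber clusters by decreasing size; ties by smallest member id
  sizes <- table(raw)
  first_member <- vapply(names(sizes), function(lbl) {
    min(names(raw)[raw == lbl])
  }, character(1))
  new_order <- names(sizes)[order(-as.integer(sizes), first_member)]
  relabel <- setNames(seq_along(new_order), new_order)

  assignments <- tibble(
    protein_group = names(raw),
    cluster = unname(relabel[as.character(raw)]),
    imputed = unname(imputed[names(raw)])
  ) %>% arrange(.data$cluster, .data$protein_group)

  structure(
    list(
      assignments = assignments,
      tree = tree,
      k = k,
      profiles = as_tibble(cbind(
        tibble(protein_group = rownames(m)), as.data.frame(m)
      ))
    ),
    class = "profile_clusters"
  )
}

#' @export
print.profile_clusters <- function(x, ...) {
  sizes <- x$assignments %>% count(.data$cluster)
  cat(sprintf(
    "Profile clustering: %d proteins in %d clusters (sizes %s)\n",
    nrow(x$assignments), x$k, paste(sizes$n, collapse = ", ")
  ))
  invisible(x)
}

#' Cluster assignments as a tibble
#'
#' @param x A `profile_clusters`.
#' @param ... Unused.
#' @return Tibble with protein_group, cluster (1..k by decreasing size) and
#'   an `imputed` flag for proteins with a missing profile entry.
#' @exportS3Method generics::tidy
tidy.profile_clusters <- function(x, ...) {
  x$assignments
}

#' One-row summary of a profile clustering
#'
#' @param x A `profile_clusters`.
#' @param ... Unused.
#' @return Tibble with n_proteins, k, and largest/smallest cluster size.
#' @exportS3Method generics::glance
glance.profile_clusters <- function(x, ...) {
  sizes <- x$assignments %>% count(.data$cluster) %>% pull(.data$n)
  tibble(
    n_proteins = nrow(x$assignments),
    k = x$k,
    largest_cluster = max(sizes),
    smallest_cluster = min(sizes)
  )
}

#' Cluster sizes
#'
#' @param x A `profile_clusters`.
#' @return Tibble with cluster and n.
#' @export
cluster_sizes <- function(x) {
  stopifnot(inherits(x, "profile_clusters"))
  x$assignments %>% count(.data$cluster)
}
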