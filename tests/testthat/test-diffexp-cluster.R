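make_sig <- function(ids, p) {
  tibble::tibble(protein_group = ids, p_value = p)
}

make_prot <- function(ids, ratio, n_unique = 3L, id = "x") {
  tibble::tibble(
    protein_group = ids,
    n_unique_peptides = n_unique,
    !!paste0("ratio_", id) := ratio,
    !!paste0("log2_", id) := log2(ratio)
  )
}

test_that("DE status applies the inclusive fold-change, alpha and peptide gates", {
  prot <- make_prot(
    sprintf("P%d", 1:6),
    ratio = c(2.0, 0.49, 4.0, 2.5, 0.5, 1.2),
    n_unique = c(2L, 3L, 3L, 1L, 2L, 5L)
  )
  sig <- make_sig(prot$protein_group, c(0.01, 0.04, 0.2, 0.01, 0.049, 0.001))
  calls <- call_differential(prot, sig, "x")
  st <- setNames(calls$status, calls$protein_group)
  expect_equal(st[["P1"]], "up") # ratio exactly 2 is inclusive
  expect_equal(st[["P2"]], "down")
  expect_equal(st[["P3"]], "ns") # fails alpha
  expect_equal(st[["P4"]], "ns") # fails min_unique
  expect_equal(st[["P5"]], "down") # ratio exactly 0.5 is inclusive
  expect_equal(st[["P6"]], "ns")

  # proteins without a ratio or p-value are not tested
  prot_na <- make_prot("P7", NA_real_)
  calls_na <- call_differential(prot_na, make_sig("P7", 0.01), "x")
  expect_equal(calls_na$status, "not_tested")

  expect_error(
    call_differential(prot, sig, "x", fc_up = 0.5, fc_down = 2),
    class = "itraqr_input_error"
  )
})

test_that("de_summary totals are up + down", {
  prot <- make_prot(sprintf("P%d", 1:10), c(4, 4, 4, 0.2, 0.2, 1, 1, 1, 1, 1))
  sig <- make_sig(prot$protein_group, rep(0.001, 10))
  calls <- call_differential(prot, sig, "x")
  s <- de_summary(calls)
  expect_equal(s$n_up, 3L)
  expect_equal(s$n_down, 2L)
  expect_equal(s$n_total, s$n_up + s$n_down)
})

test_that("DE calling at default thresholds recovers planted 4-fold changes", {
  cfg <- sim_config(
    n_proteins = 2000, frac_de = 0.1, log2fc_magnitude = 2,
    tech_noise_sd = 0.2,
    peptides_per_protein_dist = c("3" = 1),
    psms_per_peptide_dist = c("1" = 1),
    frac_low_confidence = 0, seed = 19
  )
  res <- quantify_sim(cfg)
  cmp <- default_comparisons()$MIIG_vs_GVO
  sig <- significance_b(res$proteins, cmp)
  calls <- call_differential(res$proteins, sig, cmp)
  truth <- res$truth$proteins

  merged <- dplyr::left_join(calls, truth, by = "protein_group")
  de_true <- merged$is_de
  called <- merged$status %in% c("up", "down")
  sensitivity <- mean(called[de_true])
  fpr <- mean(called[!de_true])
  expect_gte(sensitivity, 0.9)
  expect_lte(fpr, 0.02)
  # directions agree for every correctly called protein
  hit <- merged[de_true & called, ]
  expect_true(all(hit$status == hit$direction))
})

test_that("clustering recovers planted profile archetypes and orderly labels", {
  set.seed(23)
  archetypes <- list(c(2, 2), c(-2, -2), c(2, -2), c(-2, 2), c(0, 2))
  profiles <- purrr::map_dfr(seq_along(archetypes), function(i) {
    tibble::tibble(
      protein_group = sprintf("A%d_%02d", i, 1:40),
      truth = i,
      log2_c1 = archetypes[[i]][1] + rnorm(40, 0, 0.2),
      log2_c2 = archetypes[[i]][2] + rnorm(40, 0, 0.2)
    )
  })
  cl <- cluster_profiles(profiles[c("protein_group", "log2_c1", "log2_c2")], k = 5)
  asg <- tidy(cl)
  merged <- dplyr::left_join(asg, profiles, by = "protein_group")
  ari <- mclust::adjustedRandIndex(merged$cluster, merged$truth)
  expect_gte(ari, 0.9)

  # labels numbered by decreasing size and invariant to row order
  sizes <- cluster_sizes(cl)
  expect_equal(sizes$cluster, seq_len(5))
  expect_true(all(diff(sizes$n) <= 0))
  shuffled <- profiles[sample.int(nrow(profiles)), ]
  cl2 <- cluster_profiles(shuffled[c("protein_group", "log2_c1", "log2_c2")], k = 5)
  expect_equal(tidy(cl2), asg)
})

test_that("clustering edge cases behave", {
  profiles <- tibble::tibble(
    protein_group = sprintf("P%d", 1:6),
    log2_a = c(1, 1.1, -1, -1.2, 3, 3.1)
  )
  # k = 1 puts everything together
  cl1 <- cluster_profiles(profiles, k = 1)
  expect_equal(unique(tidy(cl1)$cluster), 1L)
  # more clusters than proteins is an input error
  expect_error(cluster_profiles(profiles, k = 10), class = "itraqr_input_error")

  # duplicated profiles land in the same cluster
  dup <- dplyr::bind_rows(profiles, profiles[1, ] |> dplyr::mutate(protein_group = "P1b"))
  cld <- tidy(cluster_profiles(dup, k = 3))
  expect_equal(
    cld$cluster[cld$protein_group == "P1"],
    cld$cluster[cld$protein_group == "P1b"]
  )

  # missing entries are imputed as 0 and flagged
  prof_na <- tibble::tibble(
    protein_group = c("P1", "P2", "P3"),
    log2_a = c(2, NA, -2),
    log2_b = c(2, 2, -2)
  )
  cln <- cluster_profiles(prof_na, k = 2)
  expect_true(tidy(cln)$imputed[tidy(cln)$protein_group == "P2"])
})

test_that("de_profiles builds the union of DE proteins across comparisons", {
  calls <- dplyr::bind_rows(
    tibble::tibble(
      protein_group = c("A", "B", "C"), comparison = "c1",
      ratio = c(4, 1, 0.2), log2_ratio = log2(ratio), p_value = 0.01,
      n_unique_peptides = 3L, status = c("up", "ns", "down")
    ),
    tibble::tibble(
      protein_group = c("A", "B"), comparison = "c2",
      ratio = c(1, 4), log2_ratio = log2(ratio), p_value = 0.01,
      n_unique_peptides = 3L, status = c("ns", "up")
    )
  )
  prof <- de_profiles(calls)
  expect_setequal(prof$protein_group, c("A", "B", "C"))
  # C was never quantified in c2 -> NA awaiting imputation
  expect_true(is.na(prof$log2_c2[prof$protein_group == "C"]))
})

test_that("overlap_summary does exact set arithmetic and is symmetric", {
  res <- overlap_summary(c("1", "2", "3"), c("2", "3", "4"))
  expect_equal(res$n_common, 2L)
  expect_equal(res$n_union, 4L)
  expect_equal(res$percent_common, 50)
  expect_equal(res$n_union, res$n_a + res$n_b - res$n_common)

  # symmetry
  rev <- overlap_summary(c("2", "3", "4"), c("1", "2", "3"))
  expect_equal(res[c("n_common", "n_union", "percent_common")],
               rev[c("n_common", "n_union", "percent_common")])

  expect_equal(overlap_summary(letters, letters)$percent_common, 100)
  expect_equal(overlap_summary(letters[1:5], letters[6:9])$percent_common, 0)
})

test_that("overlap percentages reproduce the published replicate agreement", {
  # 2,461 proteins shared of a 3,763-protein union -> 65%
  common <- sprintf("C%04d", 1:2461)
  only_a <- sprintf("A%04d", 1:651)
  only_b <- sprintf("B%04d", 1:651)
  res <- overlap_summary(c(common, only_a), c(common, only_b))
  expect_equal(res$n_union, 3763L)
  expect_equal(res$percent_common, 65)

  # 3,166 quantified of 3,763 identified -> 84%
  identified <- sprintf("P%04d", 1:3763)
  res2 <- overlap_summary(identified, identified[1:3166])
  expect_equal(res2$percent_common, 84)
})
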