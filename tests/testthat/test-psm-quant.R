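test_that("read_psm_table validates schema and reports offending rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  psms <- make_psms(c(100, 100, 100, 100, 50, 60, 70, 80))
  readr::write_tsv(psms, path)
  expect_equal(nrow(read_psm_table(path)), 2)

  # missing reporter column is a schema error naming the column
  readr::write_tsv(psms[setdiff(names(psms), "I117")], path)
  expect_error(read_psm_table(path), "I117", class = "itraqr_input_error")

  # negative intensity names the row
  bad <- psms
  bad$I115[2] <- -5
  readr::write_tsv(bad, path)
  expect_error(read_psm_table(path), "row 2", class = "itraqr_input_error")

  # header-only file is fine
  readr::write_tsv(psms[0, ], path)
  expect_equal(nrow(read_psm_table(path)), 0)
})

test_that("filter_psms applies the confidence and complete-reporter gates", {
  # 10 records: 3 with a zero channel, 2 (disjoint) low-confidence
  intens <- rep(c(100, 100, 100, 100), 10)
  psms <- make_psms(intens)
  psms$I115[1:3] <- 0
  psms$confidence <- 0.001
  psms$confidence[4:5] <- 0.2

  kept <- suppressMessages(filter_psms(psms, min_confidence = 0.01))
  expect_equal(nrow(kept), 5)
  counts <- attr(kept, "filter_counts")
  expect_equal(unname(counts["low_confidence"]), 2L)
  expect_equal(unname(counts["incomplete_reporter"]), 3L)

  # everything confident and complete is retained
  all_ok <- make_psms(rep(1, 8), confidence = 0.001)
  expect_equal(nrow(suppressMessages(filter_psms(all_ok))), 2)

  # completeness gate can be disabled
  kept2 <- suppressMessages(filter_psms(psms, require_complete = FALSE))
  expect_equal(nrow(kept2), 8)
})

test_that("isotope correction solves the mixing system", {
  # identity is a no-op
  psms <- make_psms(c(95, 5, 0, 0))
  out <- correct_isotope_impurities(psms, correction_matrix(diag(4)))
  expect_equal(as.data.frame(out), as.data.frame(psms))

  # tag 114 leaks 5% into channel 115: observed (95, 5, 0, 0) was pure 114.
  # Expected vector computed by an independent solve of the 4x4 system.
  m <- diag(4)
  m[1, 1] <- 0.95
  m[2, 1] <- 0.05
  oracle <- solve(m, c(95, 5, 0, 0))
  expect_equal(oracle, c(100, 0, 0, 0)) # closed form for this matrix
  corrected <- correct_isotope_impurities(psms, correction_matrix(m))
  expect_equal(
    unname(unlist(corrected[1, paste0("I", c(114, 115, 116, 117))])),
    oracle,
    tolerance = 1e-12
  )

  # singular matrix is rejected
  sing <- matrix(0.25, 4, 4)
  expect_error(correction_matrix(sing), class = "itraqr_input_error")
})

test_that("forward mixing then correction is the identity", {
  set.seed(71)
  for (rep in 1:20) {
    # random diagonally dominant mixing matrix with column sums <= 1
    m <- diag(4) * 0.9
    for (j in 1:4) {
      leak <- stats::runif(3, 0, 0.03)
      m[setdiff(1:4, j), j] <- leak
    }
    x <- matrix(stats::runif(40, 0, 1e6), ncol = 4)
    observed <- x %*% t(m)
    psms <- make_psms(as.vector(t(observed)))
    corrected <- correct_isotope_impurities(psms, correction_matrix(m))
    expect_equal(
      unname(as.matrix(corrected[paste0("I", c(114, 115, 116, 117))])),
      unname(x),
      tolerance = 1e-9
    )
  }
})

test_that("peptide roll-up averages PSMs per channel", {
  psms <- make_psms(
    c(
      100, 10, 1, 1,
      200, 30, 3, 1
    ),
    peptide = "pepA", protein = "P1"
  )
  pep <- rollup_peptides(psms)
  expect_equal(nrow(pep), 1)
  expect_equal(pep$n_psms, 2L)
  expect_equal(pep$I114, 150)
  expect_equal(pep$I115, 20)
  expect_equal(pep$I116, 2)

  # single-PSM peptides pass through unchanged; one row per peptide
  many <- make_psms(rep(c(5, 6, 7, 8), 50))
  pep2 <- rollup_peptides(many)
  expect_equal(nrow(pep2), 50)
  expect_equal(unique(pep2$I117), 8)
})

test_that("protein ratios are geometric means of unique-peptide ratios", {
  cmp <- comparison("t", "116", "114")
  # two unique peptides with 116/114 ratios 2 and 8 -> protein ratio 4
  psms <- make_psms(
    c(
      100, 1, 200, 1,
      100, 1, 800, 1
    ),
    peptide = c("a", "b"), protein = "P1"
  )
  prot <- compute_protein_ratios(rollup_peptides(psms), cmp, quiet = TRUE)
  expect_equal(prot$ratio_t, 4)

  # reciprocal ratios average to 1
  psms2 <- make_psms(
    c(
      100, 1, 50, 1,
      100, 1, 200, 1
    ),
    peptide = c("a", "b"), protein = "P1"
  )
  prot2 <- compute_protein_ratios(rollup_peptides(psms2), cmp, quiet = TRUE)
  expect_equal(prot2$ratio_t, 1)

  # A-vs-B times B-vs-A is exactly 1
  rev_cmp <- comparison("rev", "114", "116")
  prot3 <- compute_protein_ratios(rollup_peptides(psms), list(cmp, rev_cmp),
    quiet = TRUE
  )
  expect_equal(prot3$ratio_t * prot3$ratio_rev, 1)
})

test_that("multi-channel denominators use the geometric channel mean", {
  cmp <- comparison("gv", "116", c("114", "115"))
  psms <- make_psms(c(100, 400, 400, 1), peptide = "a", protein = "P1")
  prot <- compute_protein_ratios(rollup_peptides(psms), cmp, quiet = TRUE)
  expect_equal(prot$ratio_gv, 400 / sqrt(100 * 400))
})

test_that("ratios are scale-equivariant and order-invariant", {
  cfg <- sim_config(n_proteins = 30, seed = 12, frac_low_confidence = 0)
  res <- quantify_sim(cfg)
  cmp <- default_comparisons()$MIIG_vs_GVO

  psms <- suppressMessages(filter_psms(res$psms))
  scaled <- psms
  scaled$I116 <- scaled$I116 * 7
  prot_scaled <- compute_protein_ratios(rollup_peptides(scaled),
    cmp,
    quiet = TRUE
  )
  base <- res$proteins
  expect_equal(
    prot_scaled$ratio_MIIG_vs_GVO,
    base$ratio_MIIG_vs_GVO[match(prot_scaled$protein_group, base$protein_group)] * 7,
    tolerance = 1e-12
  )

  shuffled <- psms[sample.int(nrow(psms)), ]
  prot_shuf <- compute_protein_ratios(rollup_peptides(shuffled),
    default_comparisons(),
    quiet = TRUE
  )
  expect_equal(as.data.frame(prot_shuf), as.data.frame(res$proteins))
})

test_that("shared peptides never influence ratios; zero sides are excluded", {
  cmp <- comparison("t", "116", "114")
  psms <- dplyr::bind_rows(
    make_psms(c(100, 1, 200, 1), peptide = "u1", protein = "P1"),
    make_psms(c(100, 1, 200, 1), peptide = "shared", protein = "P1;P2",
              is_unique = FALSE),
    make_psms(c(0, 1, 300, 1), peptide = "u2", protein = "P1") # zero on denom
  )
  prot <- suppressMessages(
    compute_protein_ratios(rollup_peptides(psms), cmp)
  )
  p1 <- prot[prot$protein_group == "P1", ]
  expect_equal(p1$ratio_t, 2) # only u1 contributes
  expect_equal(p1$n_unique_peptides, 2L)
  # the shared group carries no unique evidence, hence no ratio
  pshared <- prot[prot$protein_group == "P1;P2", ]
  expect_true(is.na(pshared$ratio_t))

  # min_unique_for_quant withholds under-supported ratios
  prot2 <- suppressMessages(
    compute_protein_ratios(rollup_peptides(psms), cmp, min_unique_for_quant = 2)
  )
  expect_true(is.na(prot2$ratio_t[prot2$protein_group == "P1"]))
})

test_that("the noise-free pipeline recovers every true protein ratio exactly", {
  cfg <- noise_free_config(n_proteins = 40, seed = 21, frac_de = 0.25)
  res <- quantify_sim(cfg)
  for (cmp in default_comparisons()) {
    want <- true_ratios(res$truth, cmp)
    got <- res$proteins[[paste0("ratio_", cmp$id)]]
    expect_equal(
      got,
      unname(want[res$proteins$protein_group]),
      tolerance = 1e-9
    )
  }
})

test_that("impurity mixing is undone end-to-end by the correction step", {
  m <- itraq4_impurity_matrix()
  cfg <- noise_free_config(n_proteins = 30, seed = 31, frac_de = 0.2,
                           impurity_matrix = m)
  res <- quantify_sim(cfg, matrix = m)
  want <- true_ratios(res$truth, default_comparisons()$MIIG_vs_GVO)
  expect_equal(
    res$proteins$ratio_MIIG_vs_GVO,
    unname(want[res$proteins$protein_group]),
    tolerance = 1e-9
  )
})

test_that("comparison objects validate their channels", {
  expect_error(comparison("x", "118", "114"), class = "itraqr_input_error")
  expect_error(comparison("x", "114", "114"), class = "itraqr_input_error")
  expect_error(comparison("x", character(), "114"), class = "itraqr_input_error")
})

test_that("the packaged correction matrix file loads and is well-formed", {
  path <- system.file("extdata", "correction_matrix.tsv", package = "itraqr")
  m <- read_correction_matrix(path)
  expect_s3_class(m, "correction_matrix")
  expect_true(all(colSums(unclass(m)) <= 1 + 1e-9))
  expect_equal(unclass(m), unclass(itraq4_impurity_matrix()), tolerance = 1e-12)
})
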