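#' Run the full quantification pipeline
#'
#' Orchestrates the stages end to end: (optional) simulation of a PSM
#' table, PSM reading and filtering, isotope-impurity correction, peptide
#' and protein roll-up, replicate QC and mixing check, Significance B per
#' comparison, DE calling, profile clustering, optional 2^-ddCt qPCR, and a
#' final report. Every stage writes its table under `out_dir`, and a
#' `manifest.json` records the configuration snapshot, input digests, seed,
#' package version and per-stage completion with row counts, so a rerun
#' with identical inputs reproduces identical tables.
#'
#' The configuration is a named list (or path to a YAML file) with blocks:
#' \describe{
#'   \item{simulate}{arguments for [sim_config()]; omit when `psms` given.}
#'   \item{psms}{path to an existing PSM TSV (ignored when simulating).}
#'   \item{correction_matrix}{path to a matrix TSV, or "identity".}
#'   \item{comparisons}{list of `list(id=, numerator=, denominator=)`;
#'     defaults to [default_comparisons()].}
#'   \item{qc_pair}{`list(numerator=, denominator=)` replicate channels for
#'     QC; omit to skip.}
#'   \item{thresholds}{min_confidence, fc_up, fc_down, alpha, min_unique,
#'     bin_size.}
#'   \item{cluster}{`list(k = 5)`; clustering is skipped (and marked so)
#'     when fewer DE proteins than k exist.}
#'   \item{qpcr}{`list(ct =, reference_gene =, calibrator_group =)`;
#'     optional.}
#' }
#'
#' @param config A list or YAML path as above.
#' @param out_dir Output directory.
#' @param seed Overrides `simulate$seed` when given.
#' @param quiet Suppress per-stage messages.
#' @return `out_dir`, invisibly; side effect: stage TSVs, `qc_report.json`,
#'   `manifest.json`, `report.md`, `report.json`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_input(sprintf("config file not found: '%s'", config))
    config <- yaml::read_yaml(config)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  th <- utils::modifyList(
    list(
      min_confidence = 0.01, fc_up = 2, fc_down = 0.5, alpha = 0.05,
      min_unique = 2, bin_size = 300
    ),
    config$thresholds %||% list()
  )
  manifest <- list(
    tool = "itraqr", version = as.character(packageVersion("itraqr")),
    config = config, stages = list(), inputs = list()
  )
  say <- function(...) if (!quiet) message(sprintf(...))
  stage_done <- function(name, n_rows) {
    manifest$stages[[name]] <<- list(
      status = "ok", rows = n_rows, finished = format(Sys.time(), usetz = TRUE)
    )
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      marker <- file.path(out_dir, paste0(name, ".partial"))
      writeLines(conditionMessage(e), marker)
      abort(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = class(e)[1], parent = e
      )
    })
  }

  # --- input stage: simulate or read --------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(seed)) sim_args$seed <- seed
    manifest$seed <- sim_args$seed %||% 1L
    psms <- run_stage("simulate", {
      cfg <- do.call(sim_config, sim_args)
      truth <- generate_ground_truth(cfg)
      tbl <- simulate_psm_table(truth, cfg)
      write_fixture(truth, tbl, out_dir)
      tbl
    })
    say("simulate: %d PSMs for %d proteins", nrow(psms),
        nrow(distinct(psms, .data$protein_group)))
    stage_done("simulate", nrow(psms))
    psm_path <- file.path(out_dir, "psms.tsv")
  } else {
    if (is.null(config$psms)) stop_input("config needs either a `simulate` block or a `psms` path")
    psm_path <- config$psms
    if (!file.exists(psm_path)) {
      stop_input(sprintf("PSM file not found: '%s'", psm_path))
    }
    psms <- run_stage("read", read_psm_table(psm_path))
    stage_done("read", nrow(psms))
  }
  manifest$inputs$psms <- unname(tools::md5sum(psm_path))

  # --- quantify ------------------------------------------------------------
  cm <- config$correction_matrix %||% "identity"
  matrix <- if (identical(cm, "identity")) {
    correction_matrix(diag(4))
  } else {
    manifest$inputs$correction_matrix <- unname(tools::md5sum(cm))
    read_correction_matrix(cm)
  }
  comparisons <- if (is.null(config$comparisons)) {
    default_comparisons()
  } else {
    as_comparison_list(purrr::map(config$comparisons, function(x) {
      comparison(x$id, x$numerator, x$denominator)
    }))
  }

  proteins <- run_stage("quantify", {
    filtered <- filter_psms(psms, th$min_confidence, quiet = quiet)
    corrected <- correct_isotope_impurities(filtered, matrix)
    peptides <- rollup_peptides(corrected)
    compute_protein_ratios(peptides, comparisons, quiet = quiet)
  })
  readr::write_tsv(proteins, file.path(out_dir, "proteins.tsv"))
  say("quantify: %d protein groups", nrow(proteins))
  stage_done("quantify", nrow(proteins))

  # --- qc -------------------------------------------------------------------
  if (!is.null(config$qc_pair)) {
    qc <- run_stage("qc", {
      pair <- comparison("qc_pair", config$qc_pair$numerator, config$qc_pair$denominator)
      replicate_qc(proteins, pair)
    })
    mix <- mixing_check(proteins)
    qc_json <- c(
      as.list(glance(qc)),
      list(
        variation_curve = list(
          pct_variation = qc$variation_curve$pct_variation,
          cum_fraction = qc$variation_curve$cum_fraction
        ),
        mixing_check = mix
      )
    )
    jsonlite::write_json(qc_json, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    say("qc: sigma_log2 = %.4f over %d proteins", qc$sigma_log2, qc$n)
    stage_done("qc", qc$n)
  }

  # --- stats + diffexp ------------------------------------------------------
  de_calls <- run_stage("diffexp", {
    purrr::map_dfr(comparisons, function(cmp) {
      sig <- significance_b(proteins, cmp, bin_size = th$bin_size)
      readr::write_tsv(
        sig %>% select("protein_group", "bin", "z", "p_value"),
        file.path(out_dir, sprintf("significance_%s.tsv", cmp$id))
      )
      call_differential(proteins, sig, cmp,
        fc_up = th$fc_up, fc_down = th$fc_down,
        alpha = th$alpha, min_unique = th$min_unique
      )
    })
  })
  readr::write_tsv(de_calls, file.path(out_dir, "de_calls.tsv"))
  summary_tbl <- de_summary(de_calls)
  readr::write_tsv(summary_tbl, file.path(out_dir, "de_summary.tsv"))
  say("diffexp: %s", paste(
    sprintf("%s %d up / %d down", summary_tbl$comparison, summary_tbl$n_up,
            summary_tbl$n_down),
    collapse = "; "
  ))
  stage_done("diffexp", nrow(de_calls))

  # --- cluster --------------------------------------------------------------
  k <- (config$cluster %||% list())$k %||% 5
  profiles <- de_profiles(de_calls)
  if (nrow(profiles) >= k && k >= 1) {
    clusters <- run_stage("cluster", cluster_profiles(profiles, k = k))
    readr::write_tsv(tidy(clusters), file.path(out_dir, "clusters.tsv"))
    say("cluster: %d DE proteins in %d clusters", nrow(profiles), k)
    stage_done("cluster", nrow(profiles))
  } else {
    say("cluster: skipped (%d DE proteins < k = %d)", nrow(profiles), k)
    manifest$stages$cluster <- list(
      status = "skipped",
      reason = sprintf("%d DE proteins < k = %d", nrow(profiles), k)
    )
  }

  # --- qpcr -----------------------------------------------------------------
  if (!is.null(config$qpcr)) {
    rq <- run_stage("qpcr", {
      ct <- read_ct_table(config$qpcr$ct)
      delta_delta_ct(ct, config$qpcr$reference_gene, config$qpcr$calibrator_group)
    })
    manifest$inputs$ct <- unname(tools::md5sum(config$qpcr$ct))
    readr::write_tsv(rq, file.path(out_dir, "rq.tsv"))
    stage_done("qpcr", nrow(rq))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  build_report(out_dir, quiet = quiet)
  invisible(out_dir)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Build a human-readable report from a completed run directory
#'
#' Collects the stage outputs (without recomputing anything) into a
#' markdown/JSON pair: DE summary per comparison, QC scalars, cluster
#' sizes, and qPCR relative quantities. Stages whose files are absent are
#' listed as not run.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param quiet Suppress the completion message.
#' @return Path of `report.md`, invisibly.
#' @export
build_report <- function(run_dir, quiet = FALSE) {
  if (!dir.exists(run_dir)) stop_input(sprintf("run directory not found: '%s'", run_dir))
  grab <- function(file) {
    p <- file.path(run_dir, file)
    if (file.exists(p)) readr::read_tsv(p, show_col_types = FALSE) else NULL
  }
  de_sum <- grab("de_summary.tsv")
  clusters <- grab("clusters.tsv")
  rq <- grab("rq.tsv")
  qc <- {
    p <- file.path(run_dir, "qc_report.json")
    if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else NULL
  }

  lines <- c("# itraqr run report", "")
  json <- list()

  lines <- c(lines, "## Replicate QC", "")
  if (is.null(qc)) {
    lines <- c(lines, "not run", "")
  } else {
    lines <- c(
      lines,
      sprintf("- proteins compared: %d", as.integer(qc$n)),
      sprintf("- sigma(log2 ratio): %.4f", qc$sigma_log2),
      sprintf("- Pearson R^2: %.4f", qc$pearson_r2),
      sprintf("- regression slope: %.4f", qc$regression_slope),
      sprintf("- within 30%% variation: %.1f%%", 100 * qc$frac_within_30),
      ""
    )
    json$qc <- qc[c("n", "sigma_log2", "pearson_r2", "regression_slope",
                    "frac_within_30")]
  }

  lines <- c(lines, "## Differential expression", "")
  if (is.null(de_sum)) {
    lines <- c(lines, "not run", "")
  } else {
    lines <- c(
      lines, "| comparison | up | down | total |", "|---|---|---|---|",
      sprintf(
        "| %s | %d | %d | %d |",
        de_sum$comparison, de_sum$n_up, de_sum$n_down, de_sum$n_total
      ), ""
    )
    json$de_summary <- de_sum
  }

  lines <- c(lines, "## Expression clusters", "")
  if (is.null(clusters)) {
    lines <- c(lines, "not run", "")
  } else {
    sizes <- clusters %>% count(.data$cluster)
    lines <- c(
      lines,
      sprintf("- %d proteins in %d clusters", nrow(clusters), nrow(sizes)),
      sprintf("  - cluster %d: %d proteins", sizes$cluster, sizes$n), ""
    )
    json$cluster_sizes <- sizes
    json$n_clustered <- nrow(clusters)
  }

  lines <- c(lines, "## qPCR (2^-ddCt)", "")
  if (is.null(rq)) {
    lines <- c(lines, "not run", "")
  } else {
    lines <- c(
      lines, "| gene | group | RQ |", "|---|---|---|",
      sprintf("| %s | %s | %.3f |", rq$gene, rq$sample_group, rq$rq), ""
    )
    json$rq <- rq
  }

  md_path <- file.path(run_dir, "report.md")
  writeLines(lines, md_path)
  jsonlite::write_json(json, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!quiet) message(sprintf("report written to %s", md_path))
  invisible(md_path)
}
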