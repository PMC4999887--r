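# itraqr

Reporter-ion quantitative proteomics for iTRAQ 4-plex designs, from
peptide-spectrum-match (PSM) tables to differential-protein lists — built
for the pooled-reference oocyte-maturation design (tags 114/115 = immature
GV sample, 116 = competent matured MII oocytes, 117 = incompetent matured
MII oocytes), and configurable for any 4-plex layout.

It is aimed at proteomics analysts who have search-engine output (one row
per PSM with four reporter intensities) and need the downstream half of the
analysis to be explicit, tested and reproducible:

* **Quantification** — FDR/completeness filtering, isotope-impurity
  correction by solving the 4×4 channel-mixing system `M·x = observed`,
  PSM→peptide averaging, and protein ratios as geometric means of
  unique-peptide ratios:
  for unique peptide *p* and comparison *N/D*,
  `r_p = geomean(I_p[N]) / geomean(I_p[D])`, and
  `R_protein = geomean_p(r_p)`.
* **Statistics** — the intensity-binned Significance B outlier p-value:
  proteins are binned by summed intensity; within a bin with median *m* and
  robust half-widths `r₊ = P84.13 − m`, `r₋ = m − P15.87`,
  `z = (x−m)/r₊` (or `(m−x)/r₋`) and `p = ½·erfc(z/√2)`.
* **QC** — technical-replicate concordance (σ of the log2 ratio, Pearson
  R², OLS slope, cumulative %-variation curve) and an equal-mixing check.
* **Differential expression** — ratio ≥ 2 or ≤ 0.5 (inclusive), p < 0.05,
  ≥ 2 unique peptides; Ward hierarchical clustering of the DE union's
  log2-ratio profiles; set-overlap summaries.
* **qPCR cross-check** — the Livak `2^−ΔΔCt` method with Welch tests on
  replicate ΔCt values.
* **Synthetic data** — a forward simulator with known ground truth (fold
  changes, impurity mixing, shared peptides, lognormal noise), so the whole
  chain is testable without raw MS data; with noise off, the pipeline
  recovers every true ratio to 1e-9.

See the methods vignette (`vignettes/itraq-quantification.Rmd`) for the
model, parameter choices and limitations.

## Worked example

```r
library(itraqr)
library(dplyr)

# a 1,000-protein 4-plex experiment with 10% true 4-fold changes
cfg   <- sim_config(n_proteins = 1000, frac_de = 0.1, seed = 42)
truth <- generate_ground_truth(cfg)
psms  <- simulate_psm_table(truth, cfg)

proteins <- psms |>
  filter_psms() |>
  correct_isotope_impurities(correction_matrix(diag(4))) |>
  rollup_peptides() |>
  compute_protein_ratios(default_comparisons())
#> filter_psms: 9576/10048 PSMs retained (472 low-confidence, 0 incomplete reporter removed)

# the two duplicate reference channels act as technical replicates
replicate_qc(proteins, comparison("tech_rep", "114", "115"))
#> Replicate QC (114 vs 115), n = 995 proteins
#>   sigma(log2 ratio):  0.1487
#>   Pearson R^2:        0.9958
#>   regression slope:   0.9613
#>   within 30% variation: 98.1%

cmp   <- default_comparisons()$MIIG_vs_GVO
sig   <- significance_b(proteins, cmp)
calls <- call_differential(proteins, sig, cmp)
de_summary(calls)
#> # A tibble: 1 × 5
#>   comparison   n_up n_down n_tested n_total
#>   <chr>       <int>  <int>    <int>   <int>
#> 1 MIIG_vs_GVO    41     38      995      79
```

The QC block says the two reference channels agree to a log2 noise floor of
σ ≈ 0.15 with R² ≈ 0.996 — quantification noise far below a 2-fold change.
The DE summary reports 79 of the 100 planted movers (the simulator's
peptide-count distribution gives 17% of proteins a single unique peptide,
and those are excluded by the two-peptide rule); direction is recovered for
every call. Clustering the DE union and plotting:

```r
sig2    <- significance_b(proteins, default_comparisons()$MIIG_vs_MIIB)
calls2  <- call_differential(proteins, sig2, default_comparisons()$MIIG_vs_MIIB)
clusters <- cluster_profiles(de_profiles(bind_rows(calls, calls2)), k = 5)
clusters
#> Profile clustering: 79 proteins in 5 clusters (sizes 26, 21, 18, 12, 2)
autoplot(clusters)   # profile lines per cluster
```

An end-to-end run (simulate → quantify → QC → stats → DE → cluster →
report) from one config, with a manifest for reproducibility:

```r
run_pipeline(list(
  simulate = list(n_proteins = 1000, frac_de = 0.1, seed = 42),
  qc_pair  = list(numerator = "114", denominator = "115")
), out_dir = "run1")
```

A command-line wrapper with one subcommand per stage is installed at
`system.file("scripts", "itraqr.R", package = "itraqr")`.

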