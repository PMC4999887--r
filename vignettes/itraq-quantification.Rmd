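---
title: "Reporter-ion quantification for iTRAQ 4-plex experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reporter-ion quantification for iTRAQ 4-plex experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itraqr)
library(dplyr)
```

## The problem

Isobaric labelling with iTRAQ 4-plex reagents lets four samples be digested,
labelled with tags of identical mass, pooled, and measured in a single
LC-MS/MS run. On fragmentation each tag releases a reporter ion at m/z
114-117 whose intensity encodes that sample's contribution to the peptide.
Relative protein abundance between samples therefore reduces to arithmetic
on reporter intensities — but only after a chain of corrections and roll-ups
whose details decide whether the final fold changes mean anything:
identification filtering, isotope-impurity deconvolution, PSM-to-peptide
averaging, unique-peptide-only ratio formation, an intensity-aware outlier
statistic, and replicate-based QC that justifies the fold-change cutoff.

itraqr implements that chain for the pooled-reference oocyte design it was
built around: tags 114 and 115 carry the same immature (germinal-vesicle)
sample, tag 116 carries competent matured (MII) oocytes and tag 117
incompetent matured oocytes, giving the two contrasts
`MIIG_vs_GVO` (116 vs the geometric mean of 114 and 115) and
`MIIG_vs_MIIB` (116 vs 117). Nothing is hard-wired to that design: channel
roles, comparisons and the QC replicate pair are all configuration.

## From PSMs to protein ratios

A PSM table has one row per identified spectrum: peptide sequence, protein
group, a uniqueness flag, a confidence score (FDR/posterior-error style,
lower is better) and the four reporter intensities.

1. **Filtering** (`filter_psms()`): keep PSMs with confidence at or below
   0.01 (a 1% identification FDR) and — because a missing reporter makes any
   ratio with that channel undefined — with all four channels strictly
   positive. Counts removed per reason are reported.
2. **Impurity correction** (`correct_isotope_impurities()`): each reagent
   lot deposits known fractions of its signal into neighbouring channels
   (isotopic satellites at ±1 and ±2 Da). With mixing matrix $M$, where
   $M_{ij}$ is the fraction of tag $j$ observed in channel $i$, the observed
   vector per PSM is $M x$; the correction solves the 4×4 system for $x$
   rather than inverting approximately. Slightly negative solutions (noise
   around zero) are clamped to 0 with a warning. Matrices with a condition
   number above 1e8 are rejected. `itraq4_impurity_matrix()` provides
   representative published percentages for examples; real analyses should
   load the reagent lot's certificate with `read_correction_matrix()`.
3. **Peptide roll-up** (`rollup_peptides()`): peptide intensity per channel
   is the arithmetic mean over that peptide's retained PSMs.
4. **Protein ratios** (`compute_protein_ratios()`): for a comparison with
   numerator channels $N$ and denominator channels $D$, each *unique*
   peptide contributes
   $r_p = \left(\prod_{c \in N} I_{pc}\right)^{1/|N|} \big/
          \left(\prod_{c \in D} I_{pc}\right)^{1/|D|}$,
   and the protein ratio is the geometric mean of its unique-peptide
   ratios. Geometric averaging is used on both levels so that log ratios are
   averaged linearly and reciprocal comparisons invert exactly
   ($r_{A/B} \, r_{B/A} = 1$). Shared peptides (assigned to more than one
   protein group, flagged `is_unique = FALSE`) never enter a ratio — their
   signal is a mixture of their parents — though they are counted in
   `n_peptides`. Peptides with a zero on either side of a comparison are
   excluded from that comparison (zeros are treated as missing, consistent
   with the complete-reporter filter). One usable unique peptide suffices to
   quantify; the stricter two-peptide rule applies at DE calling.

Per-channel protein intensities (sums over unique peptides) are carried
along: `summed_intensity`, their total, is the abundance proxy used for
binning in the outlier statistic, and the individual channel sums feed
replicate QC.

## The Significance B outlier statistic

Ratio scatter depends strongly on abundance — dim proteins have noisy
ratios — so a global null would over-call dim proteins and under-call bright
ones. `significance_b()` sorts quantified proteins by `summed_intensity`,
cuts them into consecutive bins of `bin_size` (default 300, a conventional
choice that leaves enough proteins per bin for stable percentiles at the
few-thousand-protein scale), and inside each bin estimates the null
log2-ratio distribution robustly from percentiles: median $m$, upper
half-width $r_+ = P_{84.13} - m$ and lower half-width $r_- = m - P_{15.87}$
(the one-sigma points of a Gaussian, immune to the outliers being tested
for). The score of a protein with log2 ratio $x$ is

$$z = \begin{cases} (x - m)/r_+ & x \ge m \\ (m - x)/r_- & x < m \end{cases}
\qquad p = \tfrac12\,\mathrm{erfc}\!\left(z/\sqrt2\right),$$

the Gaussian upper-tail probability. The one-sided form is the convention
for this statistic (each protein is scored against its own direction);
`two_sided = TRUE` doubles and caps the p-value, which is the form whose
rejection rate at threshold $\alpha$ converges to $\alpha$ on a symmetric
null (the one-sided form rejects both tails, converging to $2\alpha$) — the
package's calibration tests check exactly these two limits at n = 10,000.

Numerical details: percentiles use linear interpolation between order
statistics (`quantile()` type 7); intensity ties are broken by protein id so
the bin partition is reproducible; a trailing bin smaller than half the bin
size is merged into its neighbour; a bin whose half-width is zero (all
ratios identical) is merged too, and an all-identical table is rejected as
degenerate. Raw p-values are used, matching the p < 0.05 convention for this
statistic; Benjamini–Hochberg can of course be applied to the returned
column (`p.adjust`) but is deliberately not the default.

## Replicate QC and the fold-change cutoff

`replicate_qc()` compares two channels that carry the same labelled sample.
It reports the standard deviation of the per-protein log2 ratio (the noise
floor of the experiment), the squared Pearson correlation and OLS slope of
the two channels' intensities, and a percent-variation distribution with
per-protein variation defined as $|I_A - I_B| / \bar I \times 100$ — the
|difference|-over-mean convention, chosen because it is symmetric in the two
replicates; the alternative $|r - 1| \times 100$ on the replicate ratio is a
monotone transform of it for small deviations. The cumulative curve of this
quantity is what motivates a fold-change cutoff well clear of technical
noise: with a replicate noise floor of $\sigma_{\log_2} \approx 0.16$, a
2-fold change sits more than six sigma out, which is why the DE thresholds
below use 2-fold rather than anything tighter.

`mixing_check()` verifies the equal-mixing design assumption (median log2
ratio of each channel against a reference near zero; default flag at
|median| > 0.5). Because the design is verified rather than corrected,
`median_normalize()` exists but is off by default.

## Differential expression and clustering

`call_differential()` applies the joint rule: ratio ≥ 2 or ≤ 0.5 (both
bounds inclusive — the upper bound is stated inclusively wherever the rule
appears, and the lower bound mirrors it), Significance-B p < 0.05, and at
least two unique peptides. Proteins without a ratio or p-value are
`not_tested`; everything else failing a gate is `ns`. `de_summary()` gives
the per-comparison up/down/total counts, with total = up + down by
construction.

`de_profiles()` collects proteins DE in at least one comparison into a
log2-ratio profile matrix, and `cluster_profiles()` groups them by Ward
agglomeration (`hclust(method = "ward.D2")`, Ward's criterion on Euclidean
distances) with the tree cut at exactly `k` clusters (default 5). Profiles
are clustered raw rather than per-protein standardized: with two comparison
dimensions, row z-scoring collapses almost all information into sign
patterns. A protein DE in one comparison but unquantified in the other gets
log2 ratio 0 imputed (no evidence of change) and an `imputed` flag. Labels
are renumbered by decreasing cluster size with ties broken by the smallest
member id, making the labelling invariant to input row order.

`overlap_summary()` covers the set-arithmetic reporting (replicate overlap,
quantified-of-identified and similar fractions), with percentages rounded
half away from zero as whole-number percentages are printed.

## The qPCR cross-check

`delta_delta_ct()` implements the Livak $2^{-\Delta\Delta C_t}$ method with
amplification efficiency fixed at 2: per gene and group,
$\Delta C_t = \overline{C_t}^{target} - \overline{C_t}^{reference}$,
$\Delta\Delta C_t$ subtracts the calibrator group, and
$RQ = 2^{-\Delta\Delta C_t}$, so the calibrator's RQ is exactly 1.
Replicates are averaged on the $\Delta C_t$ scale (the Livak convention);
per-replicate $\Delta C_t$ values are retained, and `compare_groups()` runs
Welch's t-test on them — the scale on which qPCR noise is closest to
normal. With the typical three replicates per group, Welch's
degrees-of-freedom approximation is mildly conservative (achieved type-I
rate a little under nominal), which the test suite documents. The reference
gene is a required argument with no default: defaulting it silently would
be worse than failing.

## The synthetic-data generator

Real 4-plex raw data are rarely redistributable, so every stage here is
exercised against `sim_config()` / `generate_ground_truth()` /
`simulate_psm_table()`, a forward model with known truth:

* **Design**: four channels, 114/115 duplicating the reference sample
  (their abundance multipliers are constrained equal), a point-mass
  |log2 FC| of 2 on the competent-MII channel for a `frac_de` fraction of
  proteins (default 0.1), direction split 50/50.
* **Peptide counts** follow the observed shape 17/11/7/6/5/54% for
  1/2/3/4/5/6+ unique peptides per protein; the open 6+ bucket is drawn
  uniformly from 6–12, a span consistent with that kind of right tail.
* **Intensities**: protein base intensity is lognormal (log2 mean 16, sd 2,
  arbitrary units); each peptide carries a lognormal ionization-efficiency
  factor (log2 sd 1) shared across channels, so it cancels in every ratio;
  each PSM observes channel intensities under independent lognormal noise
  (`tech_noise_sd` on the log2 scale, default 0.2) — multiplicative noise is
  the natural choice given that replicate log ratios are close to normal.
* **Confounds on demand**: forward impurity mixing by any
  `correction_matrix`, shared peptides (summing their parents' signal,
  flagged non-unique), and a fraction of low-confidence PSMs for the filter
  to remove.
* **Determinism**: `generate_ground_truth()` consumes one RNG stream seeded
  at `seed`, `simulate_psm_table()` one seeded at `seed + 1`; the caller's
  RNG state is untouched, and identical configs yield byte-identical
  fixtures via `write_fixture()`.

With noise off and identity mixing, the full pipeline recovers every true
ratio to 1e-9 — the package's strongest correctness oracle. What the
generator does *not* emulate: real peptide sequences and their chemistry
(sequences are synthetic identifiers), missed cleavages, ratio compression
from co-isolation interference, LC-fraction batch structure, or
intensity-dependent noise. Passing tests therefore demonstrate the
arithmetic chain is right, not that any instrument behaves this benignly;
in particular, real iTRAQ ratios are compressed toward 1, so recovered
sensitivities here are upper bounds.

## Pipeline, reporting and problem sizes

`run_pipeline()` chains the stages from a single config (list or YAML),
writes each stage's TSV plus a `manifest.json` (config snapshot, input MD5
digests, seed, per-stage row counts and timestamps), and `build_report()`
assembles a markdown/JSON report strictly by reading the stage files —
never recomputing — so report and tables cannot drift apart. A thin
command-line wrapper with one subcommand per stage ships in
`inst/scripts/itraqr.R`.

The test and acceptance workloads use simulation sizes chosen to make
Monte-Carlo error comfortably smaller than the tolerances being checked
while staying quick on a laptop: 10,000 proteins for the Significance-B
calibration (3 binomial SEs ≈ 0.009 on a 0.10 target), 5,000 single-peptide
proteins for the noise-floor readout (SE of the sd estimate ≈ 0.0016
against a ±0.01 band), 2,000 proteins at 10% DE for sensitivity/FPR, and
5 × 40 planted archetypes for clustering recovery.

## Known limitations

* No protein inference: uniqueness is taken from the input flag, and
  semicolon-joined group ids are treated as opaque labels.
* No normalization across LC fractions or runs; the package assumes one
  pooled 4-plex mixture per PSM table.
* Significance B models each bin's null as Gaussian in the tails; heavy
  tails in real ratio distributions make its extreme p-values optimistic.
* The Livak method assumes perfect doubling per cycle; efficiency-corrected
  variants are out of scope.
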