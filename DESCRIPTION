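Package: itraqr
Title: Reporter-Ion Quantitative Proteomics for iTRAQ 4-plex Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for iTRAQ 4-plex reporter-ion
    quantification: reading and filtering peptide-spectrum-match (PSM)
    tables, isotope-impurity correction of reporter intensities,
    PSM-to-peptide-to-protein roll-up with protein ratios formed as
    geometric means of unique-peptide ratios, the intensity-binned
    Significance B outlier statistic, technical-replicate concordance QC,
    differential-expression calling with fold-change and p-value
    thresholds, hierarchical clustering of expression profiles, set
    overlap summaries, and 2^-ddCt relative quantification for qPCR
    cross-checks. Includes a synthetic PSM-table generator with known
    ground truth so every stage is testable without raw mass-spectrometry
    data, and an end-to-end pipeline runner with a reproducible manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
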