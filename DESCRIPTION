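Package: methgap
Title: Gap-Based Detection and Ranking of Differentially Methylated
    CpG Sites on Infinium Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Heuristic, annotation-aware detection and ranking of
    differentially methylated CpG sites between two sample groups on
    Illumina Infinium-style methylation arrays. Sites are called by a
    minimum beta-value gap between non-overlapping groups, with greedy
    per-site masking of heterogeneous samples (for example, contaminated
    tumor specimens), and ranked by a score that rewards inter-group
    separation while penalising intra-group spread. Includes sample
    quality control from beta-value distributions and detection p-values
    (Kolmogorov-Smirnov flagging), gene-region summarisation of
    candidate sites, per-gene methylation profiles with probe-sequence
    FASTA export, multi-method candidate-list comparison with a
    median-difference post-filter, and a synthetic-data generator with
    planted ground truth. Readers are provided for beta-value and
    GenomeStudio-style signal matrices and the Illumina manifest CSV
    dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
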