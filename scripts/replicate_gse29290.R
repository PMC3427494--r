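#!/usr/bin/env Rscript
# Replication of the published breast tumor vs normal analysis on GEO
# series GSE29290 (8 tumor + 8 normal, HumanMethylation450).
#
# This script needs large external inputs that are not bundled with the
# package. Stage them under scratch/GSE29290/ as:
#
#   GSE29290_beta.tsv            beta-value matrix (probes x 16 samples,
#                                tab-delimited, first column = probe ID),
#                                extracted from the GEO series matrix
#   GSE29290_detection_pvals.tsv detection p-values, same layout
#   manifest.csv                 Illumina HumanMethylation450_15017482_v.1.1
#                                manifest CSV
#   design.tsv                   two tab-separated columns: sample ID,
#                                group label ("normal" / "tumor")
#
# Expected outputs, matching the published analysis: 480,917 sites survive
# filtering (detection p > 0.05 in any of the 16 samples, or any missing
# beta, excludes a site); 5740 detected sites at d = 0.1, m = 1; 15,047 at
# m = 2; 5282 genes carry at least one detected site at m = 2.

suppressPackageStartupMessages(library(methgap))

data_dir <- file.path("scratch", "GSE29290")
stopifnot(dir.exists(data_dir))

ds <- read_beta_matrix(file.path(data_dir, "GSE29290_beta.tsv"),
                       file.path(data_dir, "GSE29290_detection_pvals.tsv"))
cat("samples:", length(ds$sample_ids), "\n")

ann <- read_manifest(file.path(data_dir, "manifest.csv"))
design <- read_group_design(file.path(data_dir, "design.tsv"))

flt <- filter_sites(ds, p_cutoff = 0.05, max_fail_samples = 0,
                    max_missing_samples = 0)
cat("sites after filtering:", length(flt$site_ids), "(expect 480917)\n")

for (m in 0:2) {
  dm <- detect_dm(flt, with_mask_limits(design, m), d = 0.1)
  cat(sprintf("detected at d=0.1, m=%d: %d\n", m, nrow(tidy(dm))))
  if (m == 2) {
    gs <- gene_summary(dm, ann, flt$site_ids)
    n_genes <- length(unique(gs$gene[gs$region == "overall" &
                                       gs$n_sites_dm > 0]))
    cat("genes with a detected site at m=2:", n_genes, "(expect 5282)\n")
    write_dm_table(dm, file.path(data_dir, "dm_d0.1_m2.tsv"), ann = ann)
  }
}
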