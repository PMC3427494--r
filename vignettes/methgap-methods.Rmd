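---
title: "Gap-based detection of differentially methylated CpG sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap-based detection of differentially methylated CpG sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methgap)
```

## The problem

Infinium-style methylation arrays report, for each interrogated CpG site
and sample, a methylated signal $M$, an unmethylated signal $U$ and a
detection p-value. Methylation is summarised as the *beta value*

$$\beta = \frac{M}{M + U + \alpha},$$

the proportion of methylated signal, with a constant offset $\alpha$
(default 100, the ecosystem convention for these arrays) that keeps
low-intensity probes from looking confidently methylated. Beta values live
on $[0, 1]$ and read directly as "fraction of DNA molecules methylated at
this site", which is what makes them attractive to clinical researchers
despite their known statistical drawbacks (heteroscedasticity in the
mid-range).

The goal addressed here is biomarker screening between two small groups of
clinical samples — tumor versus normal tissue being the canonical case.
Rank-based tests are underpowered at $n = 8 + 8$, return statistically
significant sites whose absolute differences are too small to verify by
bisulfite sequencing, and degrade further when some "tumor" samples are
partly normal tissue from a resection margin. `methgap` implements a
deliberately simple geometric alternative.

## The detector

For one site, let the two groups' beta values be point sets on $[0, 1]$.
Order the groups by their medians and define the **gap**
(`beta_val_dist`) as

$$\mathrm{gap} = \min(\text{upper group}) - \max(\text{lower group}).$$

A positive gap means the groups are disjoint intervals; the site is called
differentially methylated when $\mathrm{gap} \ge d$, a user threshold in
beta units (0.1 in the workflows this package mirrors). Because the gap is
computed from extremes, a single aberrant sample destroys it — which is
exactly what motivates **masking**. With per-group limits
$m = (m_1, m_2)$, the detector iterates:

1. test the unmasked samples for $\mathrm{gap} \ge d$; stop on success;
2. recompute each group's median over its unmasked samples, and among
   samples whose group has not exhausted its limit, mask the single sample
   most distant from its own group median — one sample per iteration,
   irrespective of group;
3. stop with failure when no maskable sample remains.

Detected sites are scored by

$$\mathrm{score} = \mathrm{gap} - (\mathrm{median\_diff} - \mathrm{gap})
                 = 2\,\mathrm{gap} - \mathrm{median\_diff},$$

where `median_diff` is the absolute difference of the group medians.
Geometrically the medians of disjoint groups are at least a gap apart, so
$\mathrm{score} \le \mathrm{gap}$, with equality exactly when both groups
are perfectly tight: the score rewards inter-group separation and
penalises intra-group spread. Sites are ranked by score; the number of
masked samples is reported alongside and should temper enthusiasm for any
candidate that needed masking.

A worked three-site example covering the canonical cases — already
separated, overlapping-but-rescuable, and low discrimination — ships as
`worked_example_dataset()`; its documented gaps and scores are recomputed
in the test suite and the acceptance script.

### Decisions the published description leaves open

The iteration above is stated in prose by the method's source material;
three details are not, and were fixed here as follows.

* **Medians refresh every iteration.** Distances are measured to the
  median of the *currently unmasked* samples. This matches the "remaining
  samples are re-tested" reading and makes the second mask in a group
  respond to the first.
* **Tie-breaking.** Two samples equidistant from their group medians are
  ordered by larger unmasked group first (preserving the smaller group's
  information), then lexicographically smallest sample ID. This makes
  detection fully deterministic; any rule here is defensible, but an
  undefined one would make results irreproducible across platforms.
* **`median_diff` uses unmasked samples only**, consistently with the gap;
  a masked sample has been declared unrepresentative and should not drag
  the median it was excluded from. Per-group beta-range constraints
  ("hypomethylated in normals": all normal betas in $[0, 0.3]$) are
  likewise evaluated on unmasked samples, after masking succeeds.
* **Score ties** are ranked by larger gap, then fewer total masked
  samples, then site ID.

Missing betas at a site are treated as absent samples: they join neither
medians nor gaps and do not consume the mask budget, but masking never
removes a group's last non-missing value. A site whose group is entirely
missing is skipped with a warning — it should have been removed by
`filter_sites()` beforehand.

## Filtering and annotation

`filter_sites()` excludes sites with more than `max_fail_samples`
low-confidence measurements (detection $p >$ `p_cutoff`, default 0.05 — a
*high* detection p-value means the signal is indistinguishable from
background) or more than `max_missing_samples` missing betas, and can
restrict to autosomes, CpG islands, or any predicate over the probe
annotation. A missing detection p-value counts as low confidence; a
dataset with no detection p-values at all skips that criterion with a
message instead of discarding everything.

The Illumina manifest reader handles the 450k CSV dialect: preamble lines,
a trailing `[Controls]` section, semicolon-packed gene and region columns
(split positionally into (gene, region) pairs and deduplicated), and the
convention that an empty island-relation field means open sea. Gene-region
summaries count, per gene and region (TSS1500, TSS200, 5'UTR, 1stExon,
Body, 3'UTR) and overall, the sites measured and the sites detected; a
site contributes once per distinct (gene, region) pair and the overall
counts are unions over regions, never sums.

## Quality control

`ks_flag_samples()` compares each sample's beta distribution against the
pooled betas of all other samples with a two-sample Kolmogorov–Smirnov
test. The leave-one-out empirical pool is used because beta-value
mixtures have no standard parametric reference. With array-scale sample
sizes the KS p-value is degenerate — everything is "significant" — so a
sample is flagged only when $p < \alpha$ (default 0.01) *and*
$D \ge$ `min_d` (default 0.05, i.e. at least a five-percentage-point
worst-case CDF discrepancy). Flagged samples are reported, never removed.
One caveat the tests make explicit: with very few samples (say 8) a single
grossly aberrant sample contaminates the pooled reference enough to lift
clean samples' $D$ near the threshold; the flag is most trustworthy at
study sizes of a dozen samples or more, and should always be read together
with the per-sample count of low-confidence measurements
(`detection_summary()`), whose agreement with the distribution flag is the
strong indicator of a technical problem.

## Comparing candidate lists

`partition_sites()` splits 2–3 candidate lists into their $2^k - 1$
exact-membership cells; `partition_genes()` maps each *list* to the genes
its sites touch and partitions the gene sets the same way, so two methods
that agree on a gene through different sites still meet in the
intersection cell. `median_diff_filter()` applies the conventional
post-filter: keep sites whose group medians differ by at least 0.2 — the
level above which findings are generally confirmable by bisulfite
sequencing. The post-filter recomputes medians over *all* samples of each
group, ignoring any masking: lists arriving from other tools carry no
masking information, and the comparison must treat every list uniformly.
The documented consequence is that a gap-detected site that passed only
via masking can fail the post-filter. `scatter_medians()` draws the
classic median-versus-median plot with per-cell counts in the legend.

## The synthetic data generator

`simulate_methylation()` exists so that every workflow is testable without
any download, with known ground truth. It emulates:

* the bimodal beta landscape: `null_unmethylated` (mean 0.08),
  `null_methylated` (0.92) and `null_intermediate` (0.50) classes, drawn
  from Beta distributions parameterised by (mean, concentration) via
  $a = \mu c$, $b = (1 - \mu)c$, identical in both groups;
* a planted differentially methylated class whose group means are
  separated by the `effect` (default 0.4 beta units), half hyper- and half
  hypomethylated in group 2;
* **heterogeneous samples** (the tumor-contamination model): designated
  samples whose planted-site means are shifted a fraction `s` toward the
  other group — with $s = 1$ they are indistinguishable from the other
  group at exactly the discriminating sites;
* missing betas and detection failures at low independent rates, plus
  designated low-quality samples in which corrupted betas (uniform noise)
  and failing detection p-values co-occur, so count-based and
  distribution-based QC must agree on them;
* round-robin synthetic annotation (5 sites per fabricated gene, cycling
  regions, island relations and chromosomes, with 50-mer probe sequences)
  so the gene-level and comparison workflows run end to end.

Defaults mirror the two-groups-of-eight study design around which the
method was built. The concentration default of 100 gives within-group
standard deviations of 0.03–0.05, a realistic technical-plus-biological
spread for these arrays; the contamination-recovery scenario used in the
acceptance checks raises it to 200 ("tight" groups) with effect 0.5 so
that planted sites are non-overlapping by construction and the scenario
isolates exactly one failure mode — the contaminated sample — rather than
compounding it with borderline within-group spread.

What the generator does **not** emulate: Infinium I/II chemistry
differences, batch and color-bias effects, spatial artefacts, or the
correlation structure of neighbouring CpGs. Tests passing on synthetic
data therefore validate the algorithmic contracts (geometry, masking,
ranking, QC logic), not robustness to those real-world artefacts — which
is why preprocessing and normalisation are deliberately out of scope and
assumed done upstream.

## Verification strategy and problem sizes

The package's checks avoid trusting the implementation with its own
verification:

* unmasked detection is cross-checked site-for-site against a one-line
  min/max interval oracle on 10,000 simulated sites;
* every greedy-masked detection on 1,000 random small-group sites is
  confirmed by brute-force enumeration of all maskings within the limits
  (the converse is *not* asserted: greedy is knowingly not exhaustive);
* the score identity, the nestedness of detections along the $d$ and $m$
  parameter chains, and the planted-recovery contrast (masking limit 1
  rescues $\ge 99\%$ of contaminated planted sites that limit 0 cannot,
  at zero false positives) run at 10,000 sites;
* the rank-sum comparator is checked for $> 0.9$ recall of planted 0.4
  shifts at $n = 8 + 8$ after Benjamini–Hochberg correction.

These sizes keep the whole suite and the acceptance script to a few
minutes on one CPU while leaving the binomial noise on every estimated
rate far below the asserted margins. The replication of the published
16-sample breast study (480,917 filtered sites; 5740 and 15,047 detected
sites at masking limits 1 and 2; 5282 genes) requires the GEO download and
the Illumina manifest, which cannot be bundled; `scripts/replicate_gse29290.R`
documents the staging layout and runs the identical pipeline when the
files are present.

## Known limitations

* The gap statistic offers no error control; it is a screening heuristic,
  and the score is a ranking device, not a test statistic. The Wilcoxon/BH
  comparator is included precisely so users can see both views.
* Masking is greedy and can miss maskings that brute force would find
  (tested, tolerated); it is also intentionally reported, since masked
  detections are weaker evidence.
* Region-level testing, covariate adjustment, paired designs, M-values,
  normalisation and probe-design correction are out of scope; feed
  preprocessed beta matrices in.
* Gene landmarks (txStart, cdsStart, TSS boundaries) are drawn only from a
  user-supplied coordinate table; the package ships no genome build and
  performs no strand arithmetic beyond placing TSS200/TSS1500 upstream of
  the supplied start.
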