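test_that("site filtering applies detection, missingness and annotation rules", {
  ds <- toy_dataset(
    list(s1 = c(0.1, 0.2, 0.5, 0.6),
         s2 = c(0.1, NA, 0.5, 0.6),
         s3 = c(0.3, 0.3, 0.4, 0.4)),
    2, 2,
    detp = list(s1 = c(0.01, 0.2, 0.04, 0.01),
                s2 = c(0.01, 0.01, 0.01, 0.01),
                s3 = c(0.01, 0.01, 0.01, NA))
  )
  # s1 has one failing p, s2 one missing beta, s3 one missing p (= failing)
  kept <- filter_sites(ds, p_cutoff = 0.05, max_fail_samples = 0,
                       max_missing_samples = 0)
  expect_equal(kept$site_ids, character(0))
  kept1 <- filter_sites(ds, max_fail_samples = 1, max_missing_samples = 0)
  expect_equal(kept1$site_ids, c("s1", "s3"))
  kept2 <- filter_sites(ds, max_fail_samples = 1, max_missing_samples = 1)
  expect_equal(kept2$site_ids, c("s1", "s2", "s3"))

  # beta-only dataset: detection-p rule vacuous, missingness still applies
  ds2 <- toy_dataset(list(s1 = c(0.1, 0.2, 0.5, 0.6),
                          s2 = c(0.1, NA, 0.5, 0.6)), 2, 2)
  expect_message(kept3 <- filter_sites(ds2), "no detection p-values")
  expect_equal(kept3$site_ids, "s1")
})

test_that("annotation predicates restrict to autosomes or islands", {
  ds <- toy_dataset(list(s1 = c(0.1, 0.2), s2 = c(0.3, 0.4),
                         s3 = c(0.5, 0.6), s4 = c(0.7, 0.8)), 1, 1,
                    detp = list(s1 = c(0.01, 0.01), s2 = c(0.01, 0.01),
                                s3 = c(0.01, 0.01), s4 = c(0.01, 0.01)))
  ann <- tibble::tibble(
    site_id = c("s1", "s2", "s3", "s4"),
    chromosome = c("1", "X", "22", "Y"),
    position = 1:4 * 100L,
    gene_assignments = rep(list(tibble::tibble(gene = character(),
                                               region = character())), 4),
    island_relation = c("Island", "Island", "OpenSea", "N_Shore"),
    design_type = "I", probe_sequence = NA_character_
  )
  expect_equal(filter_sites(ds, ann = ann, autosomes_only = TRUE)$site_ids,
               c("s1", "s3"))
  expect_equal(filter_sites(ds, ann = ann, islands_only = TRUE)$site_ids,
               c("s1", "s2"))
  expect_equal(filter_sites(ds, ann = ann, autosomes_only = TRUE,
                            islands_only = TRUE)$site_ids, "s1")
  expect_equal(
    filter_sites(ds, ann = ann,
                 keep = function(a) a$position > 150)$site_ids,
    c("s2", "s3", "s4"))
  # site absent from annotation is removed with a warning
  ds5 <- toy_dataset(list(s1 = c(0.1, 0.2), s9 = c(0.1, 0.2)), 1, 1,
                     detp = list(s1 = c(0.01, 0.01), s9 = c(0.01, 0.01)))
  expect_warning(kept <- filter_sites(ds5, ann = ann, autosomes_only = TRUE),
                 "absent from annotation")
  expect_equal(kept$site_ids, "s1")
})

test_that("group gap is the distance between nearest unmasked values", {
  gd <- toy_design(2, 2)
  expect_equal(group_gap(c(a1 = 0.1, a2 = 0.2, b1 = 0.5, b2 = 0.6), gd), 0.3)
  expect_equal(group_gap(c(a1 = 0.1, a2 = 0.6, b1 = 0.5, b2 = 0.9), gd),
               -0.1)
  expect_equal(group_gap(c(a1 = 0.1, a2 = 0.6, b1 = 0.5, b2 = 0.9), gd,
                         masked = "a2"), 0.4)
  # orientation follows the group medians, not the group order
  expect_equal(group_gap(c(a1 = 0.8, a2 = 0.9, b1 = 0.1, b2 = 0.2), gd), 0.6)
  expect_error(group_gap(c(a1 = NA, a2 = NA, b1 = 0.5, b2 = 0.9), gd),
               "group exhausted")
})

test_that("greedy masking follows the most-distant-from-median rule", {
  gd <- toy_design(3, 3, m = c(1, 1))
  x <- c(a1 = 0.10, a2 = 0.15, a3 = 0.55, b1 = 0.60, b2 = 0.65, b3 = 0.70)
  res <- mask_and_test(x, gd, d = 0.3)
  expect_true(res$passed)
  expect_equal(res$masked, list(A = "a3", B = character()))
  expect_equal(res$gap, 0.45)

  gd0 <- toy_design(2, 2, m = c(0, 0))
  expect_true(mask_and_test(c(a1 = 0.1, a2 = 0.2, b1 = 0.5, b2 = 0.6),
                            gd0, d = 0.1)$passed)
  r <- mask_and_test(c(a1 = 0.1, a2 = 0.5, b1 = 0.5, b2 = 0.9), gd0,
                     d = 0.2)
  expect_false(r$passed)
  expect_equal(lengths(r$masked), c(A = 0L, B = 0L))

  expect_error(mask_and_test(x, gd, d = 0), "\\(0, 1\\]")
  expect_error(mask_and_test(x, gd, d = 1.2), "\\(0, 1\\]")
})

test_that("masking is one sample per iteration, irrespective of group", {
  # both groups have an outlier; group B's is more distant and goes first,
  # then the gap is reached without touching group A's limit
  gd <- toy_design(3, 3, m = c(1, 1))
  x <- c(a1 = 0.20, a2 = 0.22, a3 = 0.55, b1 = 0.80, b2 = 0.82, b3 = 0.15)
  res <- mask_and_test(x, gd, d = 0.3)
  expect_true(res$passed)
  expect_equal(res$masked$B, "b3")  # most distant overall goes first
  expect_equal(res$masked$A, "a3")  # second iteration: A's outlier
  expect_equal(res$gap, 0.80 - 0.22)
})

test_that("equidistant masking candidates break ties deterministically", {
  # distances to group medians all equal; larger group is preferred
  gd <- toy_design(4, 3, m = c(1, 1))
  # binary-exact values so the distances tie exactly
  x <- c(a1 = 0.25, a2 = 0.50, a3 = 0.50, a4 = 0.75,
         b1 = 0.125, b2 = 0.375, b3 = 0.25)
  res <- mask_and_test(x, gd, d = 0.9)
  # first masked sample must come from the 4-sample group; among the two
  # maximally distant (a1, a4: distance 0.25) the lexicographically smallest
  expect_equal(res$masked$A[1], "a1")
})

test_that("the score is gap minus the excess of median difference", {
  expect_equal(dm_score(0.4, 0.5), 0.3)
  expect_equal(dm_score(0.6, 0.6), 0.6)  # tight groups: maximum score
  expect_error(dm_score(0.5, 0.4), "median_diff")
  expect_error(dm_score(0, 0.1), "positive")

  # composed from group_gap and medians on a toy site
  gd <- toy_design(2, 2)
  x <- c(a1 = 0.1, a2 = 0.2, b1 = 0.5, b2 = 0.6)
  gap <- group_gap(x, gd)
  md <- abs(median(x[1:2]) - median(x[3:4]))
  expect_equal(gap, 0.3)
  expect_equal(md, 0.4)
  expect_equal(dm_score(gap, md), 0.2)
})

test_that("score identity holds for random valid gap/median pairs", {
  set.seed(11)
  n <- 10000
  gap <- runif(n, 1e-6, 1)
  md <- pmin(1, gap + runif(n, 0, 1 - gap))
  expect_identical(dm_score(gap, md), 2 * gap - md)
})

test_that("detection ranks by score with deterministic tie-breaking", {
  ds <- toy_dataset(list(site1 = c(0.1, 0.1, 0.6, 0.6),
                         site2 = c(0.1, 0.2, 0.5, 0.6)), 2, 2)
  dm <- detect_dm(ds, toy_design(2, 2), d = 0.1)
  rec <- tidy(dm)
  expect_equal(rec$site_id, c("site1", "site2"))
  expect_equal(rec$score, c(0.5, 0.2))
  expect_equal(rec$rank, 1:2)
  expect_equal(rec$direction, rep("hyper_in_group2", 2))

  # ranks are always a total order 1..n
  sim <- plain_sim(2000)
  r <- tidy(detect_dm(sim$dataset, sim$design, d = 0.2))
  expect_equal(r$rank, seq_len(nrow(r)))
  expect_false(is.unsorted(-r$score))
})

test_that("every record satisfies the score and geometry invariants", {
  sim <- cached("contaminated_small", contaminated_sim(3000))
  dm <- detect_dm(sim$dataset, with_mask_limits(sim$design, 1), d = 0.3)
  rec <- tidy(dm)
  expect_gt(nrow(rec), 100)
  expect_equal(rec$score, 2 * rec$beta_val_dist - rec$median_diff)
  expect_true(all(rec$beta_val_dist >= 0.3))
  expect_true(all(rec$median_diff >= rec$beta_val_dist - 1e-12))
  expect_true(all(rec$score <= rec$beta_val_dist + 1e-12))
  expect_true(all(rec$n_masked_g1 <= 1 & rec$n_masked_g2 <= 1))
})

test_that("unmasked detection agrees with the min/max oracle", {
  set.seed(21)
  n <- 2000
  b <- matrix(runif(n * 8), n, 8,
              dimnames = list(sprintf("cg%05d", 1:n),
                              c(sprintf("a%d", 1:4), sprintf("b%d", 1:4))))
  ds <- beta_dataset(b)
  gd <- toy_design(4, 4)
  d <- 0.05
  got <- detected_sites(detect_dm(ds, gd, d = d))
  want <- rownames(b)[vapply(seq_len(n), function(i) {
    gap_oracle(b[i, 1:4], b[i, 5:8]) >= d
  }, logical(1))]
  expect_setequal(got, want)
  expect_gt(length(want), 0)
})

test_that("greedy masking never detects a site brute force cannot", {
  set.seed(31)
  for (trial in 1:300) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    m <- c(sample(0:2, 1), sample(0:2, 1))
    m <- pmin(m, c(n1, n2) - 1L)
    b1 <- round(runif(n1), 2); b2 <- round(runif(n2), 2)
    x <- c(b1, b2)
    names(x) <- c(sprintf("a%d", 1:n1), sprintf("b%d", 1:n2))
    gd <- toy_design(n1, n2, m = m)
    d <- sample(c(0.1, 0.2, 0.3), 1)
    res <- mask_and_test(x, gd, d)
    if (res$passed) {
      expect_true(exhaustive_detect(b1, b2, d, m[1], m[2]),
                  label = sprintf("trial %d greedy pass confirmed", trial))
    }
  }
})

test_that("detection is monotone in the mask limit and in d", {
  sim <- cached("plain_small", plain_sim(3000))
  ds <- sim$dataset
  des <- sim$design
  det <- function(m, d) detected_sites(detect_dm(ds, with_mask_limits(des, m),
                                                 d = d))
  s_m0 <- det(0, 0.1); s_m1 <- det(1, 0.1); s_m2 <- det(2, 0.1)
  expect_true(all(s_m0 %in% s_m1))
  expect_true(all(s_m1 %in% s_m2))
  expect_gt(length(s_m0), 0)
  s_d2 <- det(1, 0.2)
  expect_true(all(s_d2 %in% s_m1))
})

test_that("range constraints keep only groups inside their interval", {
  ds <- toy_dataset(list(hypo_ok = c(0.05, 0.10, 0.60, 0.70),
                         hypo_no = c(0.35, 0.40, 0.80, 0.90)), 2, 2)
  # require group A (e.g., normals) to be hypomethylated: all betas <= 0.3
  gd <- toy_design(2, 2, range_constraints = list(A = c(0, 0.3)))
  got <- detected_sites(detect_dm(ds, gd, d = 0.2))
  expect_equal(got, "hypo_ok")
  # without the constraint both pass
  expect_setequal(detected_sites(detect_dm(ds, toy_design(2, 2), d = 0.2)),
                  c("hypo_ok", "hypo_no"))
  # constraints are evaluated on unmasked samples only
  gd2 <- toy_design(3, 2, m = c(1, 0),
                    range_constraints = list(A = c(0, 0.3)))
  ds2 <- toy_dataset(list(rescued = c(0.05, 0.10, 0.55, 0.70, 0.80)), 3, 2)
  expect_equal(detected_sites(detect_dm(ds2, gd2, d = 0.2)), "rescued")
})

test_that("sites with an all-missing group are skipped with a warning", {
  ds <- toy_dataset(list(ok = c(0.1, 0.1, 0.9, 0.9),
                         gone = c(NA, NA, 0.5, 0.6)), 2, 2)
  expect_warning(dm <- detect_dm(ds, toy_design(2, 2), d = 0.1),
                 "no non-missing")
  expect_equal(detected_sites(dm), "ok")
})

test_that("wilcoxon comparator finds planted shifts and respects nulls", {
  # identical group distributions: nothing significant
  ds0 <- toy_dataset(list(s1 = c(0.2, 0.4, 0.2, 0.4),
                          s2 = c(0.7, 0.9, 0.7, 0.9)), 2, 2)
  w0 <- wilcoxon_dm(ds0, toy_design(2, 2))
  expect_equal(significant_sites(w0), character(0))

  # constant site: p = 1 by convention
  dsc <- toy_dataset(list(s1 = c(0.5, 0.5, 0.5, 0.5)), 2, 2)
  expect_equal(wilcoxon_dm(dsc, toy_design(2, 2))$p_value, 1)

  # single tested site: BH is the identity
  ds1 <- toy_dataset(list(s1 = c(0.1, 0.2, 0.8, 0.9)), 2, 2)
  w1 <- wilcoxon_dm(ds1, toy_design(2, 2))
  expect_equal(w1$p_adjusted, w1$p_value)

  # planted shift recovery at 8 + 8
  sim <- cached("wilcox_sim", plain_sim(4000, seed = 77))
  w <- wilcoxon_dm(sim$dataset, sim$design)
  planted <- sim$truth$sites$site_id[sim$truth$sites$planted]
  recall <- mean(planted %in% significant_sites(w))
  expect_gt(recall, 0.9)
})

test_that("gene summaries count measured and detected sites per region", {
  # fixture: one gene with 14 measured sites, 5 detected
  mk_pair <- function(gene, region) tibble::tibble(gene = gene,
                                                   region = region)
  ids <- sprintf("cg%02d", 1:16)
  ann <- tibble::tibble(
    site_id = ids,
    chromosome = "1", position = seq_along(ids) * 100L,
    gene_assignments = c(
      rep(list(mk_pair("CHAD", "TSS200")), 7),
      rep(list(mk_pair("CHAD", "Body")), 7),
      list(mk_pair(c("G1", "G2"), c("TSS200", "Body"))),
      list(tibble::tibble(gene = character(), region = character()))
    ),
    island_relation = "Island", design_type = "I",
    probe_sequence = NA_character_
  )
  universe <- ids
  detected <- c(ids[1:4], ids[8], ids[15])
  gs <- gene_summary(detected, ann, universe)
  chad <- gs[gs$gene == "CHAD", ]
  expect_equal(chad$n_sites_measured[chad$region == "overall"], 14L)
  expect_equal(chad$n_sites_dm[chad$region == "overall"], 5L)
  expect_equal(chad$n_sites_dm[chad$region == "TSS200"], 4L)
  expect_equal(chad$n_sites_dm[chad$region == "Body"], 1L)
  # multi-gene probe increments both genes once each
  expect_equal(gs$n_sites_dm[gs$gene == "G1" & gs$region == "overall"], 1L)
  expect_equal(gs$n_sites_dm[gs$gene == "G2" & gs$region == "overall"], 1L)
  expect_true(all(gs$n_sites_dm <= gs$n_sites_measured))

  # no detected sites: measured counts remain
  gs0 <- gene_summary(character(), ann, universe)
  expect_true(all(gs0$n_sites_dm == 0L))
  expect_equal(gs0$n_sites_measured[gs0$gene == "CHAD" &
                                      gs0$region == "overall"], 14L)
})

test_that("overall gene counts are unions, not sums, across regions", {
  # one site annotated to both TSS200 and Body of the same gene
  ann <- tibble::tibble(
    site_id = c("cg01", "cg02"),
    chromosome = "1", position = c(100L, 200L),
    gene_assignments = list(
      tibble::tibble(gene = c("G", "G"), region = c("TSS200", "Body")),
      tibble::tibble(gene = "G", region = "Body")
    ),
    island_relation = "Island", design_type = "I",
    probe_sequence = NA_character_
  )
  gs <- gene_summary("cg01", ann, c("cg01", "cg02"))
  g <- gs[gs$gene == "G", ]
  expect_equal(g$n_sites_measured[g$region == "overall"], 2L)
  expect_equal(g$n_sites_measured[g$region == "Body"], 2L)
  expect_equal(g$n_sites_measured[g$region == "TSS200"], 1L)
  expect_equal(g$n_sites_dm[g$region == "overall"], 1L)
})
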