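test_that("two-list partition enumerates exact membership", {
  p <- partition_sites(list(A = c("1", "2"), B = c("2", "3")))
  expect_equal(sort(names(p$site_cells)), sort(c("A", "B", "A&B")))
  expect_equal(p$site_cells$A, "1")
  expect_equal(p$site_cells$B, "3")
  expect_equal(p$site_cells$`A&B`, "2")
})

test_that("three identical lists collapse into the triple intersection", {
  ids <- sprintf("cg%02d", 1:5)
  p <- partition_sites(list(X = ids, Y = ids, Z = ids))
  expect_equal(length(p$site_cells), 7L)
  expect_equal(sort(p$site_cells$`X&Y&Z`), sort(ids))
  expect_true(all(lengths(p$site_cells[names(p$site_cells) != "X&Y&Z"]) == 0))
})

test_that("three-list partition matches brute-force membership enumeration", {
  A <- as.character(1:5); B <- as.character(4:8); C <- c("5", "8", "9")
  p <- partition_sites(list(A = A, B = B, C = C))
  universe <- as.character(1:9)
  # independent brute force: classify every ID by its membership triple
  want <- split(universe, vapply(universe, function(id) {
    paste(c("A", "B", "C")[c(id %in% A, id %in% B, id %in% C)],
          collapse = "&")
  }, character(1)))
  for (cell in names(p$site_cells)) {
    expect_setequal(p$site_cells[[cell]],
                    if (cell %in% names(want)) want[[cell]] else character(0))
  }
  # cells are disjoint and cover the union
  all_ids <- unlist(p$site_cells, use.names = FALSE)
  expect_equal(sort(all_ids), sort(universe))
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_equal(sum(tidy(p)$n_sites), 9L)
})

test_that("partitioning rejects bad inputs", {
  expect_error(partition_sites(list(A = "1")), "2 or 3")
  expect_error(partition_sites(list(A = "1", A = "2")), "duplicate")
  expect_error(partition_sites(list("1", "2")), "named")
})

test_that("partition is invariant under list relabelling", {
  A <- as.character(1:5); B <- as.character(4:8)
  p1 <- partition_sites(list(A = A, B = B))
  p2 <- partition_sites(list(B = B, A = A))
  expect_setequal(p1$site_cells$`A&B`, p2$site_cells$`B&A`)
  expect_setequal(p1$site_cells$A, p2$site_cells$A)
  expect_setequal(p1$site_cells$B, p2$site_cells$B)
})

toy_gene_ann <- function(map) {
  # map: named list site_id -> character vector of genes
  tibble::tibble(
    site_id = names(map),
    chromosome = "1",
    position = seq_along(map) * 10L,
    gene_assignments = purrr::map(map, function(gs) {
      tibble::tibble(gene = gs, region = rep("Body", length(gs)))
    }),
    island_relation = "OpenSea", design_type = "I",
    probe_sequence = NA_character_
  )
}

test_that("gene-level cells follow per-list gene sets, not site cells", {
  # two lists sharing no site but hitting the same gene meet at gene level
  ann <- toy_gene_ann(list(cg01 = "GENE1", cg02 = "GENE1", cg03 = "GENE2"))
  p <- partition_sites(list(A = "cg01", B = c("cg02", "cg03")))
  p <- partition_genes(p, ann)
  expect_equal(p$gene_cells$`A&B`, "GENE1")
  expect_equal(p$gene_cells$B, "GENE2")
  expect_equal(p$gene_cells$A, character(0))

  # a site annotated to two genes in list A only puts both in A-only
  ann2 <- toy_gene_ann(list(cg01 = c("G1", "G2"), cg02 = "G3"))
  p2 <- partition_genes(partition_sites(list(A = "cg01", B = "cg02")), ann2)
  expect_setequal(p2$gene_cells$A, c("G1", "G2"))

  # unannotated sites contribute no genes, with a warning
  ann3 <- toy_gene_ann(list(cg01 = "G1"))
  expect_warning(
    p3 <- partition_genes(partition_sites(list(A = c("cg01", "cgXX"),
                                               B = "cg01")), ann3),
    "no gene annotation")
  expect_equal(p3$gene_cells$`A&B`, "G1")
})

test_that("gene-level partition matches hand enumeration on a 10-site toy", {
  ann <- toy_gene_ann(list(
    cg01 = "GA", cg02 = "GA", cg03 = "GB", cg04 = "GB", cg05 = "GC",
    cg06 = "GC", cg07 = "GD", cg08 = "GD", cg09 = "GA", cg10 = "GC"))
  A <- c("cg01", "cg03", "cg05")           # genes GA GB GC
  B <- c("cg02", "cg04", "cg07")           # genes GA GB GD
  C <- c("cg09", "cg10")                   # genes GA GC
  p <- partition_genes(partition_sites(list(A = A, B = B, C = C)), ann)
  expect_equal(p$gene_cells$`A&B&C`, "GA")
  expect_equal(p$gene_cells$`A&B`, "GB")
  expect_equal(p$gene_cells$`A&C`, "GC")
  expect_equal(p$gene_cells$B, "GD")
  expect_true(all(lengths(p$gene_cells[c("A", "C", "B&C")]) == 0))
})

test_that("median-difference post-filter retains hand-counted survivors", {
  ds <- toy_dataset(list(
    s1 = c(0.30, 0.30, 0.55, 0.55),   # diff 0.25 -> retained at 0.2
    s2 = c(0.40, 0.40, 0.50, 0.50),   # diff 0.10 -> dropped
    s3 = c(0.10, 0.10, 0.90, 0.90),   # diff 0.80 -> retained
    s4 = c(0.50, 0.50, 0.70, 0.70),   # diff 0.20 -> retained (boundary)
    s5 = c(0.45, 0.55, 0.50, 0.52)    # diff 0.01 -> dropped
  ), 2, 2)
  gd <- toy_design(2, 2)
  got <- median_diff_filter(c("s1", "s2", "s3", "s4", "s5"), ds, gd,
                            min_diff = 0.2)
  expect_equal(got, c("s1", "s3", "s4"))
  # min_diff 0 is the identity on sites present in the dataset
  expect_equal(median_diff_filter(c("s1", "s2"), ds, gd, min_diff = 0),
               c("s1", "s2"))
  expect_warning(
    got2 <- median_diff_filter(c("s1", "zzz"), ds, gd, min_diff = 0.2),
    "absent")
  expect_equal(got2, "s1")
})

test_that("the post-filter is monotone in its threshold", {
  sim <- cached("plain_small", plain_sim(3000))
  ids <- sim$dataset$site_ids
  a <- median_diff_filter(ids, sim$dataset, sim$design, min_diff = 0.3)
  b <- median_diff_filter(ids, sim$dataset, sim$design, min_diff = 0.41)
  expect_true(all(b %in% a))
  expect_gt(length(a), length(b))
})

test_that("unmasked detections always pass a post-filter at min_diff <= d", {
  sim <- cached("plain_small", plain_sim(3000))
  dm <- detect_dm(sim$dataset, sim$design, d = 0.2)  # m = 0: no masking
  ids <- detected_sites(dm)
  expect_gt(length(ids), 0)
  kept <- median_diff_filter(ids, sim$dataset, sim$design, min_diff = 0.2)
  expect_setequal(kept, ids)
})

test_that("median scatterplots carry one legend entry per cell", {
  sim <- cached("plain_small", plain_sim(3000))
  ids <- sim$dataset$site_ids
  set.seed(9)
  p <- partition_sites(list(A = sample(ids, 200), B = sample(ids, 200),
                            C = sample(ids, 200)))
  g <- scatter_medians(p, sim$dataset, sim$design)
  expect_equal(length(levels(g$data$cell)), 7L)
  tf <- tempfile(fileext = ".png")
  scatter_medians(p, sim$dataset, sim$design, path = tf)
  expect_true(file.exists(tf) && file.size(tf) > 0)
  # post-filtered input leaves the diagonal band empty
  filt <- median_diff_filter(ids, sim$dataset, sim$design, min_diff = 0.2)
  pf <- partition_sites(list(A = intersect(p$site_cells$A, filt),
                             B = intersect(p$site_cells$B, filt)))
  gf <- scatter_medians(pf, sim$dataset, sim$design)
  expect_true(all(abs(gf$data$m1 - gf$data$m2) >= 0.2))
})
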