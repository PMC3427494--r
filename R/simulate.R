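#' Configuration for the synthetic Infinium-like data generator
#'
#' Defaults emulate the breast tumor-versus-normal study design the method
#' is built around: two groups of 8 samples, a mostly-null site mixture with
#' the characteristic bimodal beta landscape (unmethylated and methylated
#' null classes plus an intermediate class), a planted differentially
#' methylated class, optional "heterogeneous" samples whose planted-site
#' betas are shifted toward the other group (tumor-contamination model),
#' and low rates of missing values and detection failures.
#'
#' @param n_sites Number of array sites (default 10000).
#' @param n_per_group Samples per group, length 2 (default `c(8, 8)`).
#' @param mixture Named proportions of the site classes
#'   `null_unmethylated`, `null_methylated`, `null_intermediate`,
#'   `dm_planted`; must sum to 1.
#' @param effect Planted group-median difference in beta units, in
#'   `(0, 1)` (default 0.4).
#' @param concentration Beta-distribution precision; betas are drawn from
#'   `Beta(mean * c, (1 - mean) * c)` (default 100, giving within-group
#'   standard deviations near 0.03-0.05).
#' @param contam_per_group Number of heterogeneous (contaminated) samples
#'   per group (default `c(0, 0)`).
#' @param contam_shift Shift fraction `s` in `[0, 1]`: at planted sites a
#'   contaminated sample's mean is `(1 - s) * own-group + s * other-group`
#'   (default 1, full contamination).
#' @param missing_rate Probability that a beta cell is missing (default
#'   0.01).
#' @param detection_fail_rate Probability that a cell's detection p-value
#'   indicates failure, independent of beta corruption (default 0.01).
#' @param n_low_quality_per_group Designated low-quality samples per group
#'   (default `c(0, 0)`); in these, a fraction of betas is replaced by
#'   uniform noise AND the same cells get failing detection p-values, so
#'   distribution-based and count-based QC agree on them.
#' @param low_quality_fraction Fraction of sites corrupted in a low-quality
#'   sample (default 0.4).
#' @param seed Integer RNG seed; generation is deterministic given the
#'   config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites = 10000,
                       n_per_group = c(8, 8),
                       mixture = c(null_unmethylated = 0.35,
                                   null_methylated = 0.35,
                                   null_intermediate = 0.20,
                                   dm_planted = 0.10),
                       effect = 0.4,
                       concentration = 100,
                       contam_per_group = c(0, 0),
                       contam_shift = 1,
                       missing_rate = 0.01,
                       detection_fail_rate = 0.01,
                       n_low_quality_per_group = c(0, 0),
                       low_quality_fraction = 0.4,
                       seed = 1) {
  cls <- c("null_unmethylated", "null_methylated", "null_intermediate",
           "dm_planted")
  if (!setequal(names(mixture), cls)) {
    stop("`mixture` must be named with the four site classes", call. = FALSE)
  }
  mixture <- mixture[cls]
  if (abs(sum(mixture) - 1) > 1e-8) {
    stop("`mixture` proportions must sum to 1", call. = FALSE)
  }
  if (effect <= 0 || effect >= 1) stop("`effect` must be in (0, 1)",
                                       call. = FALSE)
  rates <- c(missing_rate, detection_fail_rate, contam_shift,
             low_quality_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]",
                                       call. = FALSE)
  if (length(n_per_group) != 2 || any(n_per_group < 1)) {
    stop("`n_per_group` must be two positive counts", call. = FALSE)
  }
  if (any(contam_per_group >= n_per_group)) {
    stop("contamination count must be smaller than the group size",
         call. = FALSE)
  }
  if (any(n_low_quality_per_group > n_per_group)) {
    stop("low-quality count cannot exceed the group size", call. = FALSE)
  }
  structure(list(
    n_sites = as.integer(n_sites), n_per_group = as.integer(n_per_group),
    mixture = mixture, effect = effect, concentration = concentration,
    contam_per_group = as.integer(contam_per_group),
    contam_shift = contam_shift, missing_rate = missing_rate,
    detection_fail_rate = detection_fail_rate,
    n_low_quality_per_group = as.integer(n_low_quality_per_group),
    low_quality_fraction = low_quality_fraction, seed = as.integer(seed)
  ), class = "sim_config")
}

class_means <- c(null_unmethylated = 0.08, null_methylated = 0.92,
                 null_intermediate = 0.50)

#' Simulate an Infinium-like methylation dataset with planted truth
#'
#' Betas are drawn from class-specific Beta distributions parameterised by
#' (mean, concentration): null classes share parameters across groups;
#' planted sites separate the group means by the configured effect, half
#' hypermethylated and half hypomethylated in group 2. Contaminated samples
#' have their planted-site means shifted toward the other group. Missing
#' cells, independent detection failures and designated low-quality samples
#' are injected afterwards. Synthetic annotation assigns sites round-robin
#' to fabricated genes, regions, islands and chromosomes so the gene-level
#' and comparison workflows are exercisable without any real manifest.
#'
#' @param config A [sim_config()].
#' @return A list with elements `dataset` ([beta_dataset()]), `annotation`
#'   (`probe_annotation` tibble), `design` ([group_design()] with mask
#'   limits 0; see [with_mask_limits()]), and `truth` (list of tibbles
#'   `sites` — `site_id`, `class`, `mean_g1`, `mean_g2`, `planted` — and
#'   `samples` — `sample_id`, `group`, `contaminated`, `low_quality`).
#'   Deterministic for a fixed config.
#' @export
simulate_methylation <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_sites
  n1 <- config$n_per_group[1]; n2 <- config$n_per_group[2]
  gnames <- c("group1", "group2")
  samples <- c(sprintf("g1_s%02d", seq_len(n1)),
               sprintf("g2_s%02d", seq_len(n2)))
  group_of <- rep(gnames, c(n1, n2))

  # class assignment with exact planted count
  counts <- round(config$mixture * n)
  counts["dm_planted"] <- round(config$mixture[["dm_planted"]] * n)
  counts[1] <- n - sum(counts[-1])
  classes <- sample(rep(names(counts), counts))
  site_ids <- sprintf("cgS%06d", seq_len(n))

  mean_g1 <- mean_g2 <- numeric(n)
  for (cl in names(class_means)) {
    mean_g1[classes == cl] <- class_means[[cl]]
    mean_g2[classes == cl] <- class_means[[cl]]
  }
  planted <- which(classes == "dm_planted")
  lo <- 0.5 - config$effect / 2
  hi <- 0.5 + config$effect / 2
  # alternate direction: odd planted sites hyper in group 2
  hyper2 <- seq_along(planted) %% 2 == 1
  mean_g1[planted] <- ifelse(hyper2, lo, hi)
  mean_g2[planted] <- ifelse(hyper2, hi, lo)

  contam <- c(seq_len(n1) <= config$contam_per_group[1],
              seq_len(n2) <= config$contam_per_group[2])
  lowq <- c(seq_len(n1) > n1 - config$n_low_quality_per_group[1],
            seq_len(n2) > n2 - config$n_low_quality_per_group[2])

  cc <- config$concentration
  beta <- matrix(NA_real_, n, n1 + n2,
                 dimnames = list(site_ids, samples))
  for (j in seq_len(n1 + n2)) {
    own <- if (group_of[j] == "group1") mean_g1 else mean_g2
    other <- if (group_of[j] == "group1") mean_g2 else mean_g1
    mu <- own
    if (contam[j]) {
      s <- config$contam_shift
      mu[planted] <- (1 - s) * own[planted] + s * other[planted]
    }
    beta[, j] <- stats::rbeta(n, mu * cc, (1 - mu) * cc)
  }

  # detection p-values: clean cells well below 0.05, failures above it
  detp <- matrix(stats::runif(n * (n1 + n2), 0, 0.01), n, n1 + n2,
                 dimnames = list(site_ids, samples))
  fail <- matrix(stats::runif(n * (n1 + n2)) < config$detection_fail_rate,
                 n, n1 + n2)
  detp[fail] <- stats::runif(sum(fail), 0.051, 1)

  # low-quality samples: corrupted betas and failing p-values co-occur
  for (j in which(lowq)) {
    bad <- sample(n, round(config$low_quality_fraction * n))
    beta[bad, j] <- stats::runif(length(bad))
    detp[bad, j] <- stats::runif(length(bad), 0.051, 1)
  }

  miss <- matrix(stats::runif(n * (n1 + n2)) < config$missing_rate,
                 n, n1 + n2)
  beta[miss] <- NA_real_

  ann <- synthetic_annotation(site_ids)
  design <- group_design(data.frame(sample_id = samples, group = group_of))
  truth <- list(
    sites = tibble::tibble(site_id = site_ids, class = classes,
                           mean_g1 = mean_g1, mean_g2 = mean_g2,
                           planted = classes == "dm_planted"),
    samples = tibble::tibble(sample_id = samples, group = group_of,
                             contaminated = contam, low_quality = lowq)
  )
  list(dataset = beta_dataset(beta, detp), annotation = ann,
       design = design, truth = truth)
}

# Round-robin fabricated genomic context: 5 sites per gene, cycling
# regions, island relations, chromosomes; positions increase along each
# chromosome.
synthetic_annotation <- function(site_ids) {
  n <- length(site_ids)
  gene_idx <- (seq_len(n) - 1) %/% 5 + 1
  genes <- sprintf("GENE%05d", gene_idx)
  regions <- region_levels[(seq_len(n) - 1) %% length(region_levels) + 1]
  islands <- island_levels[(seq_len(n) - 1) %% length(island_levels) + 1]
  chroms <- as.character(((gene_idx - 1) %% 22) + 1)
  pos_in_chrom <- stats::ave(seq_len(n), chroms, FUN = seq_along)
  chars <- sample(c("A", "C", "G", "T"), 50 * n, replace = TRUE)
  seqs <- do.call(paste0, as.data.frame(matrix(chars, nrow = n),
                                        stringsAsFactors = FALSE))
  ann <- tibble::tibble(
    site_id = site_ids,
    chromosome = chroms,
    position = 10000L + 137L * as.integer(pos_in_chrom),
    gene_assignments = purrr::map2(genes, regions,
                                   ~ tibble::tibble(gene = .x, region = .y)),
    island_relation = islands,
    design_type = rep_len(c("I", "II"), n),
    probe_sequence = seqs
  )
  class(ann) <- c("probe_annotation", class(ann))
  ann
}

#' Rebuild a design with different mask limits
#'
#' Convenience for re-running [detect_dm()] at several masking settings on
#' the same grouping.
#'
#' @param design A [group_design()].
#' @param mask_limits New per-group limits (length 1 or 2).
#' @param range_constraints Optional new range constraints (default: keep).
#' @return A [group_design()].
#' @export
with_mask_limits <- function(design, mask_limits,
                             range_constraints = design$range_constraints) {
  df <- data.frame(
    sample_id = unlist(design$groups, use.names = FALSE),
    group = rep(design$group_names, lengths(design$groups))
  )
  group_design(df, mask_limits = mask_limits,
               range_constraints = range_constraints)
}

#' Hand-sized worked example of the three detection cases
#'
#' A 3-site, two-groups-of-three dataset realising the canonical cases of
#' the gap test at `d = 0.3`, `m = (1, 1)`:
#' \describe{
#'   \item{site_nonoverlap}{groups already separated: passes with no
#'     masking (gap 0.40, median diff 0.50, score 0.30).}
#'   \item{site_overlap}{one heterogeneous sample overlaps the other group:
#'     fails at `m = 0`, passes after masking it (gap 0.45, median diff
#'     0.525, score 0.375).}
#'   \item{site_lowdisc}{groups separated by less than `d`: fails at
#'     `m = 0`, passes after one mask with a score (0.26) below the
#'     non-overlapping site's.}
#' }
#'
#' @return A list with `dataset`, `design` (mask limits `c(1, 1)`), `d`
#'   (0.3) and `expected` (tibble of the documented outcomes per site:
#'   `site_id`, `passes_m0`, `passes_m1`, `gap`, `median_diff`, `score`,
#'   the m=1 values).
#' @export
worked_example_dataset <- function() {
  samples <- c("n1", "n2", "n3", "t1", "t2", "t3")
  beta <- rbind(
    site_nonoverlap = c(0.10, 0.15, 0.20, 0.60, 0.65, 0.70),
    site_overlap    = c(0.10, 0.15, 0.55, 0.60, 0.65, 0.70),
    site_lowdisc    = c(0.30, 0.38, 0.48, 0.70, 0.72, 0.74)
  )
  colnames(beta) <- samples
  detp <- matrix(0.001, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  design <- group_design(
    data.frame(sample_id = samples,
               group = rep(c("normal", "tumor"), each = 3)),
    mask_limits = c(1, 1)
  )
  expected <- tibble::tibble(
    site_id = rownames(beta),
    passes_m0 = c(TRUE, FALSE, FALSE),
    passes_m1 = c(TRUE, TRUE, TRUE),
    gap = c(0.40, 0.45, 0.32),
    median_diff = c(0.50, 0.525, 0.38),
    score = c(0.30, 0.375, 0.26)
  )
  list(dataset = beta_dataset(beta, detp), design = design, d = 0.3,
       expected = expected)
}
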