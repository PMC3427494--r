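#' Gene-region summary of differentially methylated sites
#'
#' For every gene annotated to at least one site of the measured universe,
#' counts the sites measured and the sites detected as differentially
#' methylated, per gene region (TSS1500, TSS200, 5'UTR, 1stExon, Body,
#' 3'UTR) and overall. A site contributes once per distinct (gene, region)
#' pair it is annotated to; the overall counts are unions over regions, not
#' sums, so a site annotated to both TSS200 and Body of one gene counts once
#' overall. This makes promoter-level enrichment of candidates visible at a
#' glance.
#'
#' @param detected A `methgap_dm` object or a character vector of detected
#'   site IDs.
#' @param ann A `probe_annotation` table covering the universe.
#' @param universe Character vector of all measured (filtered) site IDs;
#'   must contain the detected sites.
#' @return A tibble with columns `gene`, `region` (a region label or
#'   `"overall"`), `n_sites_measured`, `n_sites_dm`, `fraction_dm`, ordered
#'   by gene then region.
#' @export
gene_summary <- function(detected, ann, universe) {
  if (inherits(detected, "methgap_dm")) detected <- detected_sites(detected)
  detected <- unique(as.character(detected))
  universe <- unique(as.character(universe))
  if (!all(detected %in% universe)) {
    stop("`universe` must contain every detected site", call. = FALSE)
  }
  pairs <- gene_region_pairs(ann)
  pairs <- dplyr::filter(pairs, .data$site_id %in% universe)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(gene = character(), region = character(),
                          n_sites_measured = integer(),
                          n_sites_dm = integer(), fraction_dm = double()))
  }
  pairs <- dplyr::mutate(pairs, dm = .data$site_id %in% detected)
  per_region <- dplyr::summarise(
    dplyr::group_by(pairs, .data$gene, .data$region),
    n_sites_measured = dplyr::n_distinct(.data$site_id),
    n_sites_dm = dplyr::n_distinct(.data$site_id[.data$dm]),
    .groups = "drop"
  )
  overall <- dplyr::summarise(
    dplyr::group_by(pairs, .data$gene),
    region = "overall",
    n_sites_measured = dplyr::n_distinct(.data$site_id),
    n_sites_dm = dplyr::n_distinct(.data$site_id[.data$dm]),
    .groups = "drop"
  )
  out <- dplyr::bind_rows(per_region, overall)
  out <- dplyr::mutate(out,
                       fraction_dm = .data$n_sites_dm / .data$n_sites_measured)
  out <- dplyr::mutate(out, region = factor(.data$region,
                                            levels = c(region_levels,
                                                       "overall")))
  out <- dplyr::arrange(out, .data$gene, .data$region)
  dplyr::mutate(out, region = as.character(.data$region))
}

#' Wilcoxon rank-sum comparator with Benjamini-Hochberg correction
#'
#' The standard statistical route to differential methylation, provided so
#' gap-based candidate lists can be compared against it (see
#' [partition_sites()]): a two-sided Wilcoxon rank-sum test per site on the
#' beta values of the two groups, BH adjustment across all tested sites.
#' Sites whose betas are constant across every sample get p = 1.
#'
#' @param ds A [beta_dataset()].
#' @param design A [group_design()] (mask limits are ignored: every
#'   non-missing sample is used).
#' @param alpha Adjusted-p cutoff defining `significant` (default 0.05).
#' @return A tibble with columns `site_id`, `p_value`, `p_adjusted`,
#'   `significant`; filter on `significant` (or use
#'   [significant_sites()]) for the candidate list.
#' @export
wilcoxon_dm <- function(ds, design, alpha = 0.05) {
  stopifnot(inherits(ds, "beta_dataset"), inherits(design, "group_design"))
  check_design_covered(design, ds)
  if (any(lengths(design$groups) < 2)) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  i1 <- match(design$groups[[1]], ds$sample_ids)
  i2 <- match(design$groups[[2]], ds$sample_ids)
  p <- vapply(seq_len(nrow(ds$beta)), function(s) {
    x <- ds$beta[s, i1]; y <- ds$beta[s, i2]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0 || length(y) == 0) return(NA_real_)
    if (length(unique(c(x, y))) == 1) return(1)
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }, numeric(1))
  padj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(
    site_id = ds$site_ids,
    p_value = p,
    p_adjusted = padj,
    significant = !is.na(padj) & padj < alpha
  )
}

#' Significant site IDs of a Wilcoxon comparator run
#'
#' @param x The tibble returned by [wilcoxon_dm()].
#' @return Character vector of site IDs with `significant == TRUE`.
#' @export
significant_sites <- function(x) {
  x$site_id[x$significant]
}
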