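#' Filter sites by detection confidence, missingness and annotation
#'
#' Removes array sites that are unreliable in too many samples before
#' differential methylation analysis: a site is dropped when the number of
#' samples with detection p-value above `p_cutoff` exceeds
#' `max_fail_samples`, or the number of missing betas exceeds
#' `max_missing_samples`, or an annotation predicate rejects it. Site order
#' is preserved.
#'
#' A missing detection p-value counts as low confidence. When the dataset
#' carries no detection p-values at all (beta-only input) the detection-p
#' criterion is not applied, with a message.
#'
#' @param ds A [beta_dataset()].
#' @param p_cutoff Detection p-value above which a measurement is considered
#'   low-confidence (default 0.05).
#' @param max_fail_samples Maximum tolerated number of low-confidence samples
#'   per site (default 0: any failed sample excludes the site).
#' @param max_missing_samples Maximum tolerated number of missing betas per
#'   site (default 0).
#' @param ann Optional `probe_annotation` table, required for the
#'   annotation-based filters below.
#' @param autosomes_only If `TRUE`, keep only sites on chromosomes
#'   `"1"`..`"22"`.
#' @param islands_only If `TRUE`, keep only sites whose island relation is
#'   `Island`.
#' @param keep Optional predicate: a function taking the annotation rows for
#'   the candidate sites and returning a logical vector.
#' @return A [beta_dataset()] containing the surviving sites.
#' @export
filter_sites <- function(ds, p_cutoff = 0.05, max_fail_samples = 0,
                         max_missing_samples = 0, ann = NULL,
                         autosomes_only = FALSE, islands_only = FALSE,
                         keep = NULL) {
  stopifnot(inherits(ds, "beta_dataset"))
  if (p_cutoff <= 0 || p_cutoff >= 1) {
    stop("`p_cutoff` must be in (0, 1)", call. = FALSE)
  }
  if (max_fail_samples < 0 || max_missing_samples < 0) {
    stop("thresholds must be >= 0", call. = FALSE)
  }
  ok <- rep(TRUE, length(ds$site_ids))
  if (all(is.na(ds$detection_p))) {
    message("dataset has no detection p-values; detection-p filter not applied")
  } else {
    n_fail <- rowSums(is.na(ds$detection_p) | ds$detection_p > p_cutoff)
    ok <- ok & n_fail <= max_fail_samples
  }
  n_missing <- rowSums(is.na(ds$beta))
  ok <- ok & n_missing <= max_missing_samples
  if (autosomes_only || islands_only || !is.null(keep)) {
    if (is.null(ann)) {
      stop("annotation-based filters need `ann`", call. = FALSE)
    }
    idx <- match(ds$site_ids, ann$site_id)
    unseen <- is.na(idx)
    if (any(unseen & ok)) {
      warning(sum(unseen & ok),
              " site(s) absent from annotation were removed")
      ok <- ok & !unseen
    }
    sub <- ann[idx, , drop = FALSE]
    if (autosomes_only) {
      ok <- ok & !is.na(sub$chromosome) &
        sub$chromosome %in% as.character(1:22)
    }
    if (islands_only) {
      ok <- ok & !is.na(sub$island_relation) & sub$island_relation == "Island"
    }
    if (!is.null(keep)) {
      verdict <- rep(FALSE, length(ok))
      verdict[!unseen] <- as.logical(keep(sub[!unseen, , drop = FALSE]))
      ok <- ok & !is.na(verdict) & verdict
    }
  }
  subset_dataset(ds, sites = which(ok))
}

#' Signed beta-value gap between two groups at one site
#'
#' The gap is the distance between the nearest unmasked beta values of the
#' two groups: with the lower group defined as the one with the smaller
#' median of unmasked betas, `gap = min(upper group) - max(lower group)`. A
#' positive gap means the groups do not overlap; a gap of at most zero means
#' they do.
#'
#' @param site_betas Named numeric vector of beta values for one site (names
#'   are sample IDs); missing values are ignored.
#' @param design A [group_design()].
#' @param masked Character vector of sample IDs to exclude.
#' @return A single signed numeric gap.
#' @examples
#' gd <- group_design(data.frame(sample_id = c("a1","a2","b1","b2"),
#'                               group = c("A","A","B","B")))
#' group_gap(c(a1 = 0.1, a2 = 0.2, b1 = 0.5, b2 = 0.6), gd)  # 0.3
#' @export
group_gap <- function(site_betas, design, masked = character()) {
  u <- split_unmasked(site_betas, design, masked)
  gap_of(u[[1]], u[[2]])
}

split_unmasked <- function(site_betas, design, masked) {
  out <- lapply(design$groups, function(ids) {
    v <- site_betas[setdiff(ids, masked)]
    v <- v[!is.na(v)]
    if (length(v) == 0) stop("group exhausted: no unmasked, non-missing ",
                             "samples remain", call. = FALSE)
    v
  })
  names(out) <- design$group_names
  out
}

gap_of <- function(u1, u2) {
  if (stats::median(u1) <= stats::median(u2)) {
    min(u2) - max(u1)
  } else {
    min(u1) - max(u2)
  }
}

#' Greedy sample masking against a minimum group gap
#'
#' Tests one site for a minimum beta-value distance `d` between
#' non-overlapping groups, masking heterogeneous samples greedily: while the
#' gap is below `d`, group medians are recomputed over the unmasked samples,
#' and among samples whose group has not reached its mask limit the one most
#' distant from its own group median is masked — one sample per iteration,
#' irrespective of group. The loop stops when the gap reaches `d` (success)
#' or no maskable sample remains (failure).
#'
#' Ties in distance are broken toward the larger unmasked group, then toward
#' the lexicographically smallest sample ID, so results are deterministic.
#'
#' @inheritParams group_gap
#' @param d Minimum gap in beta units, in `(0, 1]`.
#' @return A list with elements `passed` (logical), `masked` (named list of
#'   masked sample IDs per group, in masking order), `gap` (the final gap).
#' @examples
#' gd <- group_design(data.frame(
#'   sample_id = c("a1","a2","a3","b1","b2","b3"),
#'   group = rep(c("A","B"), each = 3)), mask_limits = c(1, 1))
#' x <- c(a1 = 0.10, a2 = 0.15, a3 = 0.55, b1 = 0.60, b2 = 0.65, b3 = 0.70)
#' mask_and_test(x, gd, d = 0.3)  # masks a3, gap 0.45
#' @export
mask_and_test <- function(site_betas, design, d) {
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d <= 0 || d > 1) {
    stop("`d` must be in (0, 1]", call. = FALSE)
  }
  gnames <- design$group_names
  limits <- design$mask_limits
  masked <- stats::setNames(list(character(), character()), gnames)
  # per-group non-missing betas; masking never empties a group because
  # mask limits are < group size, but missingness can, checked here
  vals <- lapply(design$groups, function(ids) {
    v <- site_betas[ids]
    v[!is.na(v)]
  })
  names(vals) <- gnames
  if (any(lengths(vals) == 0)) {
    stop("group exhausted: no unmasked, non-missing samples remain",
         call. = FALSE)
  }
  repeat {
    u <- list(vals[[1]][setdiff(names(vals[[1]]), masked[[1]])],
              vals[[2]][setdiff(names(vals[[2]]), masked[[2]])])
    gap <- gap_of(u[[1]], u[[2]])
    if (gap >= d) {
      return(list(passed = TRUE, masked = masked, gap = gap))
    }
    meds <- c(stats::median(u[[1]]), stats::median(u[[2]]))
    best_id <- NA_character_
    best_g <- NA_integer_
    best <- c(dist = -Inf, size = -Inf)
    for (g in 1:2) {
      if (length(masked[[g]]) >= limits[g]) next
      ug <- u[[g]]
      # never mask a group down to zero non-missing samples
      if (length(ug) <= 1) next
      dist <- unname(abs(ug - meds[g]))
      size <- length(ug)
      for (k in seq_along(ug)) {
        id <- names(ug)[k]
        better <- dist[k] > best[["dist"]] ||
          (dist[k] == best[["dist"]] && size > best[["size"]]) ||
          (dist[k] == best[["dist"]] && size == best[["size"]] &&
             !is.na(best_id) && id < best_id)
        if (better) {
          best <- c(dist = dist[k], size = size)
          best_id <- id
          best_g <- g
        }
      }
    }
    if (is.na(best_id)) {
      return(list(passed = FALSE, masked = masked, gap = gap))
    }
    masked[[best_g]] <- c(masked[[best_g]], best_id)
  }
}

#' Differential methylation score from gap and median difference
#'
#' `score = beta_val_dist - (median_diff - beta_val_dist)`, i.e.
#' `2 * beta_val_dist - median_diff`: the inter-group gap, penalised by the
#' intra-group spread (the excess of the median difference over the gap).
#' Higher discrimination between groups and lower variability within groups
#' both increase the score; its maximum, attained when each group is
#' perfectly tight, equals the gap itself.
#'
#' @param beta_val_dist Positive gap between non-overlapping groups.
#' @param median_diff Absolute difference of the two group medians; by
#'   geometry it is at least the gap, which is enforced.
#' @return The numeric score (vectorised over its arguments).
#' @examples
#' dm_score(0.4, 0.5)  # 0.3
#' @export
dm_score <- function(beta_val_dist, median_diff) {
  if (any(beta_val_dist <= 0)) {
    stop("`beta_val_dist` must be positive", call. = FALSE)
  }
  if (any(median_diff < beta_val_dist - 1e-12)) {
    stop("`median_diff` must be >= `beta_val_dist` (internal invariant ",
         "violated)", call. = FALSE)
  }
  2 * beta_val_dist - median_diff
}

#' Detect and rank differentially methylated sites
#'
#' Runs the gap-with-masking test ([mask_and_test()]) at every site of a
#' (typically pre-filtered, see [filter_sites()]) dataset, applies the
#' design's per-group beta-range constraints to the unmasked samples of the
#' surviving sites, scores each detected site with [dm_score()], and ranks
#' by score. The median difference and the hyper/hypomethylation direction
#' are computed on unmasked samples only, consistently with the gap. Sites
#' whose detection required masking are recognisable by `n_masked_total > 0`.
#'
#' Score ties are ordered by larger gap, then fewer total masked samples,
#' then site ID.
#'
#' @param ds A [beta_dataset()].
#' @param design A [group_design()]; its `mask_limits` give the per-group
#'   maximum number of masked samples, its `range_constraints` the optional
#'   per-group beta intervals.
#' @param d Minimum beta-value gap between non-overlapping groups (default
#'   0.1).
#' @return An object of class `methgap_dm`; use [tidy()][tidy.methgap_dm()]
#'   for the per-site table and [glance()][glance.methgap_dm()] for the
#'   one-row run summary. The tidy table has columns `rank`, `site_id`,
#'   `score`, `beta_val_dist`, `median_diff`, `direction`
#'   (`hyper_in_group2`/`hypo_in_group2`, group 2 being the second level of
#'   the design), `n_masked_g1`, `n_masked_g2`, `n_masked_total`,
#'   `masked_g1`, `masked_g2` (comma-separated sample IDs).
#' @export
detect_dm <- function(ds, design, d = 0.1) {
  stopifnot(inherits(ds, "beta_dataset"), inherits(design, "group_design"))
  check_design_covered(design, ds)
  gnames <- design$group_names
  i1 <- match(design$groups[[1]], ds$sample_ids)
  i2 <- match(design$groups[[2]], ds$sample_ids)
  B <- ds$beta
  n_sites <- nrow(B)
  skipped <- 0L
  rows <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    x <- B[s, ]
    v1 <- x[i1]; v2 <- x[i2]
    if (all(is.na(v1)) || all(is.na(v2))) {
      skipped <- skipped + 1L
      next
    }
    res <- mask_and_test(x, design, d)
    if (!res$passed) next
    u1 <- v1[!is.na(v1) & !(names(v1) %in% res$masked[[1]])]
    u2 <- v2[!is.na(v2) & !(names(v2) %in% res$masked[[2]])]
    if (!range_ok(u1, u2, design)) next
    med1 <- stats::median(u1); med2 <- stats::median(u2)
    median_diff <- abs(med1 - med2)
    rows[[s]] <- list(
      site_id = ds$site_ids[s],
      score = dm_score(res$gap, median_diff),
      beta_val_dist = res$gap,
      median_diff = median_diff,
      direction = if (med2 > med1) "hyper_in_group2" else "hypo_in_group2",
      n_masked_g1 = length(res$masked[[1]]),
      n_masked_g2 = length(res$masked[[2]]),
      masked_g1 = paste(res$masked[[1]], collapse = ","),
      masked_g2 = paste(res$masked[[2]], collapse = ",")
    )
  }
  if (skipped > 0) {
    warning(skipped, " site(s) had a group with no non-missing values and ",
            "were not tested")
  }
  rec <- dplyr::bind_rows(rows)
  if (nrow(rec) == 0) {
    rec <- tibble::tibble(
      site_id = character(), score = double(), beta_val_dist = double(),
      median_diff = double(), direction = character(),
      n_masked_g1 = integer(), n_masked_g2 = integer(),
      masked_g1 = character(), masked_g2 = character()
    )
  }
  rec <- dplyr::mutate(rec,
                       n_masked_total = .data$n_masked_g1 + .data$n_masked_g2)
  rec <- dplyr::arrange(rec, dplyr::desc(.data$score),
                        dplyr::desc(.data$beta_val_dist),
                        .data$n_masked_total, .data$site_id)
  rec <- dplyr::mutate(rec, rank = dplyr::row_number(), .before = 1)
  structure(
    list(records = rec, d = d, mask_limits = design$mask_limits,
         group_names = gnames, n_sites_tested = n_sites - skipped,
         n_samples = stats::setNames(lengths(design$groups), gnames)),
    class = "methgap_dm"
  )
}

range_ok <- function(u1, u2, design) {
  rc <- design$range_constraints
  if (is.null(rc)) return(TRUE)
  u <- stats::setNames(list(u1, u2), design$group_names)
  for (g in names(rc)) {
    if (any(u[[g]] < rc[[g]][1] | u[[g]] > rc[[g]][2])) return(FALSE)
  }
  TRUE
}

#' @export
print.methgap_dm <- function(x, ...) {
  cat(sprintf(
    "<methgap_dm> %d sites detected of %d tested (d=%g, m=(%d,%d))\n",
    nrow(x$records), x$n_sites_tested, x$d,
    x$mask_limits[1], x$mask_limits[2]))
  cat(sprintf("  groups: %s (n=%d) vs %s (n=%d)\n",
              x$group_names[1], x$n_samples[1],
              x$group_names[2], x$n_samples[2]))
  if (nrow(x$records) > 0) print(utils::head(x$records, 5))
  invisible(x)
}

#' @rdname detect_dm
#' @param x A `methgap_dm` object.
#' @param ... Unused.
#' @method tidy methgap_dm
#' @export
tidy.methgap_dm <- function(x, ...) x$records

#' @rdname detect_dm
#' @method glance methgap_dm
#' @export
glance.methgap_dm <- function(x, ...) {
  tibble::tibble(
    n_sites_tested = x$n_sites_tested,
    n_detected = nrow(x$records),
    n_detected_masked = sum(x$records$n_masked_total > 0),
    d = x$d,
    m_g1 = unname(x$mask_limits[1]),
    m_g2 = unname(x$mask_limits[2])
  )
}

#' Site IDs detected by a differential methylation run
#'
#' @param x A `methgap_dm` object.
#' @return Character vector of detected site IDs in rank order.
#' @export
detected_sites <- function(x) {
  stopifnot(inherits(x, "methgap_dm"))
  x$records$site_id
}
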