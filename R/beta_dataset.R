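#' Construct a beta-value dataset
#'
#' The central container of the package: a sites-by-samples matrix of
#' methylation beta values (proportions in `[0, 1]`) with a parallel matrix of
#' detection p-values. Rows are CpG sites (probe identifiers such as
#' `cg00000029`), columns are samples. Either matrix may contain `NA` cells;
#' the detection-p matrix may be entirely missing (beta-only input, common for
#' GEO series-matrix exports that ship only beta values).
#'
#' @param beta Numeric matrix of beta values with unique rownames (site IDs)
#'   and unique colnames (sample IDs). All non-missing entries must lie in
#'   `[0, 1]`.
#' @param detection_p Optional numeric matrix of detection p-values with the
#'   same dimensions and dimnames as `beta`. If `NULL`, an all-`NA` matrix is
#'   used.
#'
#' @return An object of class `beta_dataset`: a list with elements `beta`,
#'   `detection_p`, `site_ids`, `sample_ids`.
#' @examples
#' b <- matrix(c(0.1, 0.9, 0.5, NA), nrow = 2,
#'             dimnames = list(c("cg01", "cg02"), c("s1", "s2")))
#' ds <- beta_dataset(b)
#' dim(ds)
#' @export
beta_dataset <- function(beta, detection_p = NULL) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop("`beta` must be a numeric matrix", call. = FALSE)
  }
  # R drops zero-length dimnames, so a dimension of length 0 (e.g. after
  # filtering away every site) legitimately has none
  if ((nrow(beta) > 0 && is.null(rownames(beta))) ||
      (ncol(beta) > 0 && is.null(colnames(beta)))) {
    stop("`beta` must have rownames (site IDs) and colnames (sample IDs)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(beta))) {
    stop("duplicated site IDs: ",
         rownames(beta)[duplicated(rownames(beta))][1], call. = FALSE)
  }
  if (anyDuplicated(colnames(beta))) {
    stop("duplicated sample IDs: ",
         colnames(beta)[duplicated(colnames(beta))][1], call. = FALSE)
  }
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0,1] at site '%s', sample '%s': %g",
                 rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
                 beta[bad[1, , drop = FALSE]]), call. = FALSE)
  }
  if (is.null(detection_p)) {
    detection_p <- matrix(NA_real_, nrow(beta), ncol(beta),
                          dimnames = dimnames(beta))
  }
  if (!identical(dim(detection_p), dim(beta))) {
    stop("`detection_p` dimensions differ from `beta`", call. = FALSE)
  }
  if (!identical(rownames(detection_p), rownames(beta)) ||
      !identical(colnames(detection_p), colnames(beta))) {
    stop("`detection_p` dimnames differ from `beta`", call. = FALSE)
  }
  badp <- which(!is.na(detection_p) & (detection_p < 0 | detection_p > 1),
                arr.ind = TRUE)
  if (nrow(badp) > 0) {
    stop(sprintf("detection p-value out of [0,1] at site '%s', sample '%s'",
                 rownames(detection_p)[badp[1, 1]],
                 colnames(detection_p)[badp[1, 2]]), call. = FALSE)
  }
  structure(
    list(beta = beta, detection_p = detection_p,
         site_ids = rownames(beta) %||% character(0),
         sample_ids = colnames(beta) %||% character(0)),
    class = "beta_dataset"
  )
}

#' @export
dim.beta_dataset <- function(x) dim(x$beta)

#' @export
print.beta_dataset <- function(x, ...) {
  cat(sprintf("<beta_dataset> %d sites x %d samples\n",
              nrow(x$beta), ncol(x$beta)))
  cat(sprintf("  missing betas: %d; detection p-values present: %s\n",
              sum(is.na(x$beta)),
              if (all(is.na(x$detection_p))) "no" else "yes"))
  invisible(x)
}

#' Subset a beta dataset by site and/or sample
#'
#' @param x A [beta_dataset()].
#' @param sites,samples Character vectors of IDs (or logical/integer indices)
#'   to keep; `NULL` keeps everything. Order of the result follows the
#'   selection.
#' @return A `beta_dataset`.
#' @export
subset_dataset <- function(x, sites = NULL, samples = NULL) {
  stopifnot(inherits(x, "beta_dataset"))
  i <- if (is.null(sites)) x$site_ids else sites
  j <- if (is.null(samples)) x$sample_ids else samples
  beta_dataset(x$beta[i, j, drop = FALSE], x$detection_p[i, j, drop = FALSE])
}

#' Tidy a beta dataset into long form
#'
#' One row per (site, sample) cell, suitable for dplyr/ggplot2 work.
#'
#' @param x A [beta_dataset()].
#' @param ... Unused.
#' @return A tibble with columns `site_id`, `sample_id`, `beta`,
#'   `detection_p`.
#' @method tidy beta_dataset
#' @export
tidy.beta_dataset <- function(x, ...) {
  tibble::tibble(
    site_id = rep(x$site_ids, times = length(x$sample_ids)),
    sample_id = rep(x$sample_ids, each = length(x$site_ids)),
    beta = as.vector(x$beta),
    detection_p = as.vector(x$detection_p)
  )
}

#' @method glance beta_dataset
#' @export
glance.beta_dataset <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x$beta),
    n_samples = ncol(x$beta),
    n_missing_beta = sum(is.na(x$beta)),
    has_detection_p = !all(is.na(x$detection_p))
  )
}
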