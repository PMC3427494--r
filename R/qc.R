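#' Per-sample detection p-value summary
#'
#' Counts, per sample, the measurements whose detection p-value exceeds the
#' cutoff (low confidence of methylation accuracy). A missing detection
#' p-value is counted as low-confidence. A rising low-confidence count is
#' the leading technical indicator of a degraded sample and should be read
#' together with the distribution-based flag of [ks_flag_samples()].
#'
#' @param ds A [beta_dataset()].
#' @param p_cutoff Detection p-value cutoff, in `(0, 1)` (default 0.05).
#' @return A tibble with columns `sample_id`, `n_measured` (non-missing
#'   betas) and `n_low_confidence`. If the dataset carries no detection
#'   p-values at all, `n_low_confidence` is `NA` with a warning rather than
#'   zero.
#' @export
detection_summary <- function(ds, p_cutoff = 0.05) {
  stopifnot(inherits(ds, "beta_dataset"))
  if (p_cutoff <= 0 || p_cutoff >= 1) {
    stop("`p_cutoff` must be in (0, 1)", call. = FALSE)
  }
  n_measured <- colSums(!is.na(ds$beta))
  if (all(is.na(ds$detection_p))) {
    warning("dataset has no detection p-values; low-confidence counts are NA")
    n_low <- rep(NA_integer_, length(ds$sample_ids))
  } else {
    n_low <- colSums(is.na(ds$detection_p) | ds$detection_p > p_cutoff)
  }
  tibble::tibble(sample_id = ds$sample_ids,
                 n_measured = as.integer(n_measured),
                 n_low_confidence = as.integer(n_low))
}

#' Flag samples with aberrant beta-value distributions
#'
#' Each sample's non-missing beta values are compared, by a two-sample
#' Kolmogorov-Smirnov test, against the pooled non-missing betas of all
#' other samples (leave-one-out empirical reference; beta-value mixtures
#' have no standard parametric form). A sample is flagged when the KS
#' p-value falls below `alpha` AND the KS statistic D reaches `min_d`: with
#' hundreds of thousands of sites the p-value alone is degenerate, so the
#' effect-size guard keeps trivial deviations from being flagged. Flagged
#' samples are reported, never removed — exclusion is the user's call.
#'
#' @param ds A [beta_dataset()] with at least 2 samples.
#' @param alpha KS p-value threshold (default 0.01).
#' @param min_d Minimum KS D statistic (default 0.05).
#' @param p_cutoff Detection p-value cutoff passed to
#'   [detection_summary()] for the counts included in the report.
#' @param min_sites Minimum non-missing betas required to test a sample
#'   (default 100); below it the sample is flagged with status
#'   `insufficient_data` and no KS test is computed.
#' @return An object of class `methgap_qc`; [tidy()] gives the per-sample
#'   table (`sample_id`, `n_measured`, `n_low_confidence`, `ks_statistic`,
#'   `ks_pvalue`, `status`, `flagged`), [glance()] the one-row summary.
#' @export
ks_flag_samples <- function(ds, alpha = 0.01, min_d = 0.05,
                            p_cutoff = 0.05, min_sites = 100) {
  stopifnot(inherits(ds, "beta_dataset"))
  if (length(ds$sample_ids) < 2) {
    stop("at least 2 samples are required", call. = FALSE)
  }
  counts <- suppressWarnings(detection_summary(ds, p_cutoff))
  n <- length(ds$sample_ids)
  D <- rep(NA_real_, n)
  P <- rep(NA_real_, n)
  status <- rep("ok", n)
  for (j in seq_len(n)) {
    x <- ds$beta[, j]
    x <- x[!is.na(x)]
    if (length(x) < min_sites) {
      status[j] <- "insufficient_data"
      next
    }
    ref <- ds$beta[, -j, drop = FALSE]
    ref <- ref[!is.na(ref)]
    kt <- suppressWarnings(stats::ks.test(x, ref))
    D[j] <- unname(kt$statistic)
    P[j] <- kt$p.value
  }
  flagged <- status == "insufficient_data" |
    (!is.na(P) & P < alpha & D >= min_d)
  tab <- tibble::tibble(
    sample_id = ds$sample_ids,
    n_measured = counts$n_measured,
    n_low_confidence = counts$n_low_confidence,
    ks_statistic = D,
    ks_pvalue = P,
    status = status,
    flagged = flagged
  )
  structure(list(samples = tab, alpha = alpha, min_d = min_d,
                 p_cutoff = p_cutoff),
            class = "methgap_qc")
}

#' @export
print.methgap_qc <- function(x, ...) {
  cat(sprintf("<methgap_qc> %d samples, %d flagged (alpha=%g, min D=%g)\n",
              nrow(x$samples), sum(x$samples$flagged), x$alpha, x$min_d))
  print(x$samples)
  invisible(x)
}

#' @rdname ks_flag_samples
#' @param x A `methgap_qc` object.
#' @param ... Unused.
#' @method tidy methgap_qc
#' @export
tidy.methgap_qc <- function(x, ...) x$samples

#' @rdname ks_flag_samples
#' @method glance methgap_qc
#' @export
glance.methgap_qc <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$samples),
    n_flagged = sum(x$samples$flagged),
    alpha = x$alpha,
    min_d = x$min_d
  )
}

#' Beta-value distribution plot per sample
#'
#' One density trace per sample on a shared `[0, 1]` beta axis; healthy
#' Infinium samples show the characteristic bimodal shape with modes near 0
#' and 1. Samples flagged by QC are drawn with a distinct linetype.
#'
#' @param ds A [beta_dataset()].
#' @param qc Optional `methgap_qc` object used to mark flagged samples.
#' @param path Optional file path; when given the plot is also saved there.
#' @return A ggplot object, invisibly when `path` is given.
#' @export
beta_distribution_plot <- function(ds, qc = NULL, path = NULL) {
  df <- tidy.beta_dataset(ds)
  df <- dplyr::filter(df, !is.na(.data$beta))
  if (nrow(df) == 0) {
    warning("no non-missing beta values; plotting empty axes")
    p <- ggplot2::ggplot() +
      ggplot2::xlim(0, 1) +
      ggplot2::labs(x = "beta value", y = "density")
  } else {
    if (!is.null(qc)) {
      fl <- qc$samples$sample_id[qc$samples$flagged]
      df$flagged <- df$sample_id %in% fl
    } else {
      df$flagged <- FALSE
    }
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$beta, colour = .data$sample_id,
      linetype = .data$flagged, group = .data$sample_id)) +
      ggplot2::geom_density(adjust = 0.8) +
      ggplot2::scale_linetype_manual(
        values = c(`FALSE` = "solid", `TRUE` = "dashed"),
        guide = if (any(df$flagged)) "legend" else "none") +
      ggplot2::coord_cartesian(xlim = c(0, 1)) +
      ggplot2::labs(x = "beta value", y = "density",
                    colour = "sample", linetype = "flagged")
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 7, height = 5)
    return(invisible(p))
  }
  p
}

#' @method autoplot methgap_qc
#' @export
autoplot.methgap_qc <- function(object, ...) {
  df <- object$samples
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_low_confidence,
                                   y = .data$ks_statistic,
                                   colour = .data$flagged)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$min_d, linetype = "dotted") +
    ggplot2::labs(x = "low-confidence measurements",
                  y = "KS statistic D vs pooled other samples",
                  colour = "flagged")
}
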