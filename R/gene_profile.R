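#' Build a per-gene methylation profile
#'
#' Collects every array site annotated to a gene, in genomic order, together
#' with the per-sample beta values and a flag for membership in a detected
#' differential methylation list. Sites that are annotated to the gene but
#' absent from the dataset (for example, removed by [filter_sites()]) are
#' reported separately, so "12 of 14 annotated sites displayed" situations
#' are visible.
#'
#' @param gene Gene symbol as used in the annotation.
#' @param ds A [beta_dataset()].
#' @param ann A `probe_annotation` table.
#' @param dm Optional `methgap_dm` object or character vector of detected
#'   site IDs.
#' @param coords Optional gene-coordinate table (data frame with columns
#'   `gene`, `chrom`, `tx_start`, `cds_start`, and optionally `strand`)
#'   supplying landmark positions for plotting; no genome build is bundled,
#'   so coordinates are always user-supplied.
#' @return An object of class `methgap_gene_profile`: list with `gene`,
#'   `sites` (tibble: `site_id`, `position`, `regions`, `dm_flag`, then one
#'   column per sample), `missing_sites` (annotated but unmeasured site
#'   IDs), `landmarks` (named numeric vector, possibly empty),
#'   `annotated_positions` (positions of all annotated sites, for stems).
#' @export
build_gene_profile <- function(gene, ds, ann, dm = NULL, coords = NULL) {
  stopifnot(inherits(ds, "beta_dataset"))
  pairs <- gene_region_pairs(ann)
  hit <- unique(pairs$site_id[pairs$gene == gene])
  if (length(hit) == 0) {
    near <- unique(pairs$gene[startsWith(toupper(pairs$gene),
                                         substr(toupper(gene), 1, 3))])
    stop("gene '", gene, "' not found in annotation",
         if (length(near) > 0)
           paste0("; near matches: ",
                  paste(utils::head(near, 5), collapse = ", ")) else "",
         call. = FALSE)
  }
  if (inherits(dm, "methgap_dm")) dm <- detected_sites(dm)
  dm <- as.character(dm %||% character())
  idx <- match(hit, ann$site_id)
  regions <- purrr::map_chr(ann$gene_assignments[idx], function(p) {
    paste(unique(p$region[p$gene == gene]), collapse = ";")
  })
  info <- tibble::tibble(site_id = hit,
                         position = ann$position[idx],
                         regions = regions)
  info <- dplyr::arrange(info, .data$position)
  measured <- info$site_id %in% ds$site_ids
  sites <- info[measured, , drop = FALSE]
  sites$dm_flag <- sites$site_id %in% dm
  betas <- ds$beta[sites$site_id, , drop = FALSE]
  sites <- dplyr::bind_cols(sites, tibble::as_tibble(betas))
  landmarks <- numeric()
  if (!is.null(coords)) {
    row <- coords[coords$gene == gene, , drop = FALSE]
    if (nrow(row) > 0) {
      landmarks <- c(txStart = as.numeric(row$tx_start[1]),
                     cdsStart = as.numeric(row$cds_start[1]))
      strand <- if ("strand" %in% names(row)) row$strand[1] else "+"
      dir <- if (identical(strand, "-")) 1 else -1
      landmarks <- c(landmarks,
                     TSS200 = landmarks[["txStart"]] + dir * 200,
                     TSS1500 = landmarks[["txStart"]] + dir * 1500)
    }
  }
  structure(
    list(gene = gene, sites = sites,
         missing_sites = info$site_id[!measured],
         landmarks = landmarks,
         annotated_positions = info$position,
         sample_ids = ds$sample_ids),
    class = "methgap_gene_profile"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.methgap_gene_profile <- function(x, ...) {
  cat(sprintf(
    "<methgap_gene_profile> %s: %d measured site(s) (%d flagged DM), %d annotated but unmeasured\n",
    x$gene, nrow(x$sites), sum(x$sites$dm_flag), length(x$missing_sites)))
  invisible(x)
}

#' @rdname build_gene_profile
#' @param x A `methgap_gene_profile` object.
#' @param ... Unused.
#' @method tidy methgap_gene_profile
#' @export
tidy.methgap_gene_profile <- function(x, ...) {
  tidyr::pivot_longer(x$sites, cols = dplyr::all_of(x$sample_ids),
                      names_to = "sample_id", values_to = "beta")
}

#' Plot a gene's methylation profile in genomic coordinates
#'
#' Beta values are plotted against genomic position, one marker per sample
#' styled by group; sites in the detected list are marked with an asterisk
#' above the panel, stems below the x-axis show every annotated CpG position
#' (measured or not), and transcription landmarks (txStart, cdsStart,
#' TSS200/TSS1500 boundaries) are drawn as labelled vertical guides when the
#' profile carries coordinates.
#'
#' @param profile A `methgap_gene_profile`.
#' @param design A [group_design()].
#' @param window Optional numeric `c(start, end)` position interval to zoom
#'   to.
#' @param path Optional file path; when given the plot is also saved.
#' @return A ggplot object, invisibly when `path` is given.
#' @export
plot_gene_profile <- function(profile, design, window = NULL, path = NULL) {
  stopifnot(inherits(profile, "methgap_gene_profile"))
  df <- tidy.methgap_gene_profile(profile)
  df <- dplyr::filter(df, !is.na(.data$beta))
  grp <- stats::setNames(
    rep(design$group_names, lengths(design$groups)),
    unlist(design$groups, use.names = FALSE))
  df$group <- unname(grp[df$sample_id])
  stems <- profile$annotated_positions
  if (!is.null(window)) {
    df <- dplyr::filter(df, .data$position >= window[1],
                        .data$position <= window[2])
    stems <- stems[stems >= window[1] & stems <= window[2]]
    if (nrow(df) == 0) {
      warning("window excludes all measured sites; plotting empty axes")
    }
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$beta,
                                        colour = .data$group,
                                        shape = .data$group)) +
    ggplot2::geom_point(alpha = 0.8, size = 2) +
    ggplot2::coord_cartesian(ylim = c(-0.08, 1.05)) +
    ggplot2::labs(title = profile$gene, x = "genomic position",
                  y = "beta value")
  if (length(stems) > 0) {
    p <- p + ggplot2::annotate("segment", x = stems, xend = stems,
                               y = -0.08, yend = -0.02, colour = "grey30")
  }
  dm_sites <- profile$sites[profile$sites$dm_flag, , drop = FALSE]
  if (!is.null(window) && nrow(dm_sites) > 0) {
    dm_sites <- dm_sites[dm_sites$position >= window[1] &
                           dm_sites$position <= window[2], , drop = FALSE]
  }
  if (nrow(dm_sites) > 0) {
    p <- p + ggplot2::annotate("text", x = dm_sites$position, y = 1.03,
                               label = "*", size = 6)
  }
  lm <- profile$landmarks
  if (!is.null(window) && length(lm) > 0) {
    lm <- lm[lm >= window[1] & lm <= window[2]]
  }
  if (length(lm) > 0) {
    p <- p +
      ggplot2::geom_vline(xintercept = unname(lm), linetype = "dashed",
                          colour = "grey50") +
      ggplot2::annotate("text", x = unname(lm), y = 0.98, label = names(lm),
                        angle = 90, vjust = -0.3, size = 3)
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 8, height = 5)
    return(invisible(p))
  }
  p
}

#' @method autoplot methgap_gene_profile
#' @export
autoplot.methgap_gene_profile <- function(object, design, window = NULL,
                                          ...) {
  plot_gene_profile(object, design, window = window)
}

#' Export a gene profile's probe sequences as FASTA
#'
#' Writes the profile's probes, ordered by genomic position, via
#' [write_probe_fasta()]; the gene's genomic sequence (if supplied) leads
#' the file. Headers carry the probe position so the sequence context of
#' each measurement is explicit.
#'
#' @param profile A `methgap_gene_profile`.
#' @param ann A `probe_annotation` table with a `probe_sequence` column.
#' @param path Output path.
#' @param gene_sequence Optional genomic DNA string for the gene region.
#' @return `path`, invisibly.
#' @export
export_gene_fasta <- function(profile, ann, path, gene_sequence = NULL) {
  stopifnot(inherits(profile, "methgap_gene_profile"))
  ids <- profile$sites$site_id
  idx <- match(ids, ann$site_id)
  seqs <- ann$probe_sequence[idx]
  if (all(is.na(seqs))) {
    stop("no probe sequences in the annotation; supply a manifest with an ",
         "AlleleA_ProbeSeq column", call. = FALSE)
  }
  keep <- !is.na(seqs)
  if (any(!keep)) {
    warning(sum(!keep), " probe(s) without a sequence were omitted")
  }
  probes <- tibble::tibble(
    site_id = ids[keep],
    probe_sequence = seqs[keep],
    position = profile$sites$position[keep]
  )
  probes <- dplyr::arrange(probes, .data$position)
  write_probe_fasta(probes, path, gene_sequence = gene_sequence,
                    gene_name = profile$gene)
  invisible(path)
}
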