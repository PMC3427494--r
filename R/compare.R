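#' Partition 2-3 candidate site lists into exact-membership cells
#'
#' Splits the union of the input lists into the `2^k - 1` nonempty-subset
#' cells of exact membership (for lists A, B: A-only, B-only, A-and-B), the
#' structure behind a Venn comparison of detection methods. Cells are
#' pairwise disjoint and their union is the union of the inputs.
#'
#' @param lists Named list of 2 or 3 character vectors of site IDs; names
#'   must be unique and non-empty.
#' @return An object of class `methgap_partition` with elements
#'   `list_names`, `site_cells` (named list keyed by labels such as
#'   `"A&B"`), and `gene_cells` (`NULL` until [partition_genes()]).
#'   [tidy()] gives per-cell counts.
#' @examples
#' p <- partition_sites(list(A = c("cg1", "cg2"), B = c("cg2", "cg3")))
#' tidy(p)
#' @export
partition_sites <- function(lists) {
  k <- length(lists)
  if (k < 2 || k > 3) stop("2 or 3 lists are required", call. = FALSE)
  nm <- names(lists)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("every list must be named", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate list names: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  lists <- lapply(lists, function(x) unique(as.character(x)))
  structure(
    list(list_names = nm,
         site_cells = membership_cells(lists),
         gene_cells = NULL,
         n_unannotated = 0L),
    class = "methgap_partition"
  )
}

# Exact-membership partition of named sets; cells keyed "A", "A&B", ...
membership_cells <- function(sets) {
  nm <- names(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 0) {
    member <- matrix(logical(0), 0, length(sets), dimnames = list(NULL, nm))
  }
  if (length(universe) == 1) member <- matrix(member, 1,
                                              dimnames = list(NULL, nm))
  cells <- list()
  subsets <- all_nonempty_subsets(nm)
  for (sub in subsets) {
    key <- paste(sub, collapse = "&")
    inside <- rowSums(member[, sub, drop = FALSE]) == length(sub) &
      rowSums(member[, setdiff(nm, sub), drop = FALSE]) == 0
    cells[[key]] <- universe[inside]
  }
  cells
}

all_nonempty_subsets <- function(nm) {
  out <- list()
  for (size in seq_along(nm)) {
    cmb <- utils::combn(nm, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Map a site-level partition to genes
#'
#' Each input list is mapped to its gene set — every gene annotated to any
#' of the list's sites — and the gene sets are partitioned by exact
#' membership, mirroring the site-level cells. Two lists sharing no site but
#' hitting the same gene therefore meet in the gene-level intersection cell.
#' Sites with no gene annotation contribute no genes and are counted in
#' `n_unannotated` with a warning.
#'
#' @param partition A `methgap_partition` from [partition_sites()].
#' @param ann A `probe_annotation` table.
#' @return The partition with `gene_cells` filled.
#' @export
partition_genes <- function(partition, ann) {
  stopifnot(inherits(partition, "methgap_partition"))
  pairs <- gene_region_pairs(ann)
  # reconstruct the original lists from the disjoint cells
  lists <- lapply(partition$list_names, function(nm) {
    keys <- names(partition$site_cells)
    unlist(partition$site_cells[
      vapply(keys, function(k) nm %in% strsplit(k, "&", fixed = TRUE)[[1]],
             logical(1))], use.names = FALSE)
  })
  names(lists) <- partition$list_names
  all_sites <- unique(unlist(lists, use.names = FALSE))
  n_nogene <- sum(!all_sites %in% pairs$site_id)
  if (n_nogene > 0) {
    warning(n_nogene, " site(s) have no gene annotation and contribute no ",
            "genes")
  }
  gene_sets <- lapply(lists, function(ids) {
    unique(pairs$gene[pairs$site_id %in% ids])
  })
  partition$gene_cells <- membership_cells(gene_sets)
  partition$n_unannotated <- n_nogene
  partition
}

#' @export
print.methgap_partition <- function(x, ...) {
  cat(sprintf("<methgap_partition> lists: %s\n",
              paste(x$list_names, collapse = ", ")))
  print(tidy.methgap_partition(x))
  invisible(x)
}

#' @rdname partition_sites
#' @param x A `methgap_partition` object.
#' @param ... Unused.
#' @method tidy methgap_partition
#' @export
tidy.methgap_partition <- function(x, ...) {
  out <- tibble::tibble(
    cell = names(x$site_cells),
    n_sites = lengths(x$site_cells)
  )
  if (!is.null(x$gene_cells)) {
    out$n_genes <- lengths(x$gene_cells)[out$cell]
  }
  out
}

#' @rdname partition_sites
#' @method glance methgap_partition
#' @export
glance.methgap_partition <- function(x, ...) {
  tibble::tibble(
    n_lists = length(x$list_names),
    n_cells = length(x$site_cells),
    n_sites_union = sum(lengths(x$site_cells)),
    n_genes_union = if (is.null(x$gene_cells)) NA_integer_ else
      sum(lengths(x$gene_cells))
  )
}

#' Post-filter a candidate list by group median beta difference
#'
#' Retains the sites whose absolute difference of group median betas is at
#' least `min_diff`. Medians are taken over all non-missing samples of each
#' group — the comparison treats lists from any method uniformly, so no
#' masking information is used. The default 0.2 is the conventional
#' threshold above which findings are robustly confirmable by bisulfite
#' sequencing.
#'
#' @param sites Character vector of site IDs.
#' @param ds A [beta_dataset()].
#' @param design A [group_design()].
#' @param min_diff Minimum absolute median difference in beta units
#'   (default 0.2).
#' @return Character vector of retained site IDs (input order preserved);
#'   sites absent from the dataset are dropped with a warning.
#' @export
median_diff_filter <- function(sites, ds, design, min_diff = 0.2) {
  stopifnot(inherits(ds, "beta_dataset"), inherits(design, "group_design"))
  if (min_diff < 0 || min_diff > 1) {
    stop("`min_diff` must be in [0, 1]", call. = FALSE)
  }
  sites <- as.character(sites)
  present <- sites %in% ds$site_ids
  if (any(!present)) {
    warning(sum(!present), " site(s) absent from the dataset were dropped")
  }
  sites <- sites[present]
  md <- site_median_diff(sites, ds, design)
  # tolerance so that differences exactly at the threshold survive rounding
  sites[!is.na(md) & md >= min_diff - 1e-9]
}

site_median_diff <- function(sites, ds, design) {
  i1 <- match(design$groups[[1]], ds$sample_ids)
  i2 <- match(design$groups[[2]], ds$sample_ids)
  rows <- match(sites, ds$site_ids)
  vapply(rows, function(s) {
    abs(stats::median(ds$beta[s, i1], na.rm = TRUE) -
          stats::median(ds$beta[s, i2], na.rm = TRUE))
  }, numeric(1))
}

#' Median-versus-median scatterplot of a list comparison
#'
#' Each site of the partition's union is drawn at (group-1 median beta,
#' group-2 median beta), coloured by its membership cell, with per-cell
#' counts in the legend. Sites on the diagonal have zero median difference;
#' a post-filtered input therefore leaves an empty band around it.
#'
#' @param partition A `methgap_partition`.
#' @param ds A [beta_dataset()].
#' @param design A [group_design()].
#' @param path Optional file path; when given the plot is also saved.
#' @return A ggplot object, invisibly when `path` is given.
#' @export
scatter_medians <- function(partition, ds, design, path = NULL) {
  stopifnot(inherits(partition, "methgap_partition"))
  cells <- partition$site_cells
  df <- dplyr::bind_rows(lapply(names(cells), function(k) {
    ids <- intersect(cells[[k]], ds$site_ids)
    if (length(ids) == 0) {
      return(tibble::tibble(site_id = character(), cell = character(),
                            m1 = double(), m2 = double()))
    }
    i1 <- match(design$groups[[1]], ds$sample_ids)
    i2 <- match(design$groups[[2]], ds$sample_ids)
    rows <- match(ids, ds$site_ids)
    tibble::tibble(
      site_id = ids,
      cell = k,
      m1 = vapply(rows, function(s)
        stats::median(ds$beta[s, i1], na.rm = TRUE), numeric(1)),
      m2 = vapply(rows, function(s)
        stats::median(ds$beta[s, i2], na.rm = TRUE), numeric(1))
    )
  }))
  counts <- lengths(cells)
  labels <- sprintf("%s (%d)", names(cells), counts)
  names(labels) <- names(cells)
  df$cell <- factor(df$cell, levels = names(cells), labels = labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$m1, y = .data$m2,
                                        colour = .data$cell)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::scale_colour_discrete(drop = FALSE) +
    ggplot2::labs(x = paste("median beta,", design$group_names[1]),
                  y = paste("median beta,", design$group_names[2]),
                  colour = "set")
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 7, height = 6)
    return(invisible(p))
  }
  p
}

#' @method autoplot methgap_partition
#' @export
autoplot.methgap_partition <- function(object, ds, design, ...) {
  scatter_medians(object, ds, design)
}
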