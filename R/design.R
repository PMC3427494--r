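#' Define a two-group sample design
#'
#' Assigns samples to exactly two named groups and carries the per-group
#' masking limits and optional per-group beta-range constraints used by
#' [detect_dm()].
#'
#' @param design A data frame with columns `sample_id` and `group` (extra
#'   columns are ignored), or a named character vector of group labels with
#'   sample IDs as names.
#' @param mask_limits Integer vector of length 2: the maximum number of
#'   samples that may be masked per group, in the order of `group_names(x)`
#'   (first level encountered first). Each limit must be strictly smaller than
#'   its group size. A single value is recycled to both groups.
#' @param range_constraints Optional named list mapping a group name to a
#'   closed interval `c(lo, hi)` within `[0, 1]`; a detected site is kept only
#'   if every unmasked beta of that group lies inside the interval (for
#'   example, "hypomethylated in normals": `list(normal = c(0, 0.3))`).
#'
#' @return An object of class `group_design` with elements `groups` (named
#'   list of sample-ID vectors), `group_names`, `mask_limits`,
#'   `range_constraints`.
#' @examples
#' gd <- group_design(data.frame(
#'   sample_id = c("n1", "n2", "t1", "t2"),
#'   group = c("normal", "normal", "tumor", "tumor")
#' ), mask_limits = c(1, 1))
#' @export
group_design <- function(design, mask_limits = c(0L, 0L),
                         range_constraints = NULL) {
  if (is.data.frame(design)) {
    if (!all(c("sample_id", "group") %in% names(design))) {
      stop("`design` data frame needs columns `sample_id` and `group`",
           call. = FALSE)
    }
    assignment <- stats::setNames(as.character(design$group),
                                  as.character(design$sample_id))
  } else if (is.character(design) && !is.null(names(design))) {
    assignment <- design
  } else {
    stop("`design` must be a data frame or a named character vector",
         call. = FALSE)
  }
  if (anyDuplicated(names(assignment))) {
    stop("duplicated sample ID in design: ",
         names(assignment)[duplicated(names(assignment))][1], call. = FALSE)
  }
  gnames <- unique(unname(assignment))
  if (length(gnames) != 2) {
    stop("exactly two groups are required, got: ",
         paste(gnames, collapse = ", "), call. = FALSE)
  }
  groups <- split(names(assignment), factor(assignment, levels = gnames))
  if (any(lengths(groups) == 0)) stop("each group must be non-empty",
                                      call. = FALSE)
  if (length(mask_limits) == 1) mask_limits <- rep(mask_limits, 2)
  mask_limits <- as.integer(mask_limits)
  if (length(mask_limits) != 2 || any(is.na(mask_limits)) ||
      any(mask_limits < 0)) {
    stop("`mask_limits` must be two non-negative integers", call. = FALSE)
  }
  if (any(mask_limits >= lengths(groups))) {
    stop("mask limit must be smaller than the group size (cannot mask an ",
         "entire group)", call. = FALSE)
  }
  names(mask_limits) <- gnames
  if (!is.null(range_constraints)) {
    if (!is.list(range_constraints) ||
        !all(names(range_constraints) %in% gnames)) {
      stop("`range_constraints` must be a named list keyed by group name",
           call. = FALSE)
    }
    for (g in names(range_constraints)) {
      iv <- range_constraints[[g]]
      if (length(iv) != 2 || any(is.na(iv)) || iv[1] > iv[2] ||
          iv[1] < 0 || iv[2] > 1) {
        stop("range constraint for group '", g,
             "' must be c(lo, hi) with 0 <= lo <= hi <= 1", call. = FALSE)
      }
    }
  }
  structure(
    list(groups = groups, group_names = gnames, mask_limits = mask_limits,
         range_constraints = range_constraints),
    class = "group_design"
  )
}

#' @export
print.group_design <- function(x, ...) {
  cat(sprintf("<group_design> %s (n=%d, m=%d) vs %s (n=%d, m=%d)\n",
              x$group_names[1], length(x$groups[[1]]), x$mask_limits[1],
              x$group_names[2], length(x$groups[[2]]), x$mask_limits[2]))
  if (!is.null(x$range_constraints)) {
    for (g in names(x$range_constraints)) {
      cat(sprintf("  range constraint %s: [%g, %g]\n", g,
                  x$range_constraints[[g]][1], x$range_constraints[[g]][2]))
    }
  }
  invisible(x)
}

#' Read a two-column sample design file
#'
#' Tab-separated, two columns (sample ID, group label), no header required.
#'
#' @param path Path to the design file.
#' @inheritParams group_design
#' @return A [group_design()].
#' @export
read_group_design <- function(path, mask_limits = c(0L, 0L),
                              range_constraints = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample_id", "group"),
                          colClasses = "character")
  group_design(df, mask_limits = mask_limits,
               range_constraints = range_constraints)
}

design_samples <- function(design) unlist(design$groups, use.names = FALSE)

check_design_covered <- function(design, ds) {
  missing <- setdiff(design_samples(design), ds$sample_ids)
  if (length(missing) > 0) {
    stop("design sample(s) absent from dataset: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
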