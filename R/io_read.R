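# Missing-value tokens accepted in matrix inputs (GEO dialects vary).
.na_tokens <- c("", "NA", "na", "Na", "nA", "NaN", "nan", "NAN",
                "null", "NULL", "Null")

read_matrix_tsv <- function(path, what = "value") {
  df <- readr::read_tsv(path, na = .na_tokens, comment = "!",
                        col_types = readr::cols(
                          readr::col_character(),
                          .default = readr::col_double()
                        ),
                        progress = FALSE, show_col_types = FALSE)
  if (ncol(df) < 2) stop("matrix file '", path, "' has no sample columns",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicated site ID in '", path, "': ", ids[duplicated(ids)][1],
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  m
}

#' Read a beta-value matrix (and optional detection p-value matrix)
#'
#' Both files are tab-delimited text with a header row of sample names and a
#' first column of probe IDs, the layout of GEO series-matrix table exports.
#' Lines starting with `!` (series-matrix metadata) are skipped. Blank cells
#' and the tokens `NA`, `NaN`, `null` (any case) are treated as missing.
#'
#' When both files are given their sample columns are matched by name and the
#' p-value columns reordered to the beta order; a sample or site present in
#' only one of the two files is an error naming the first offending ID.
#'
#' @param beta_path Path to the beta-value matrix.
#' @param pval_path Optional path to the detection p-value matrix. If `NULL`
#'   the returned dataset has an all-missing detection-p matrix.
#' @return A [beta_dataset()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("ID_REF\ts1\ts2", "cg01\t0.1\t0.9", "cg02\t0.5\tNA"), tf)
#' ds <- read_beta_matrix(tf)
#' @export
read_beta_matrix <- function(beta_path, pval_path = NULL) {
  beta <- read_matrix_tsv(beta_path)
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value outside [0,1] in '%s' at row '%s', column '%s': %g",
      beta_path, rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
      beta[bad[1, , drop = FALSE]]), call. = FALSE)
  }
  pv <- NULL
  if (!is.null(pval_path)) {
    pv <- read_matrix_tsv(pval_path)
    pv <- align_parallel_matrix(beta, pv, beta_path, pval_path)
  }
  beta_dataset(beta, pv)
}

# Match a parallel matrix to the beta layout by site and sample NAME;
# any ID present on one side only is a hard error.
align_parallel_matrix <- function(beta, other, beta_path, other_path) {
  ms <- setdiff(rownames(beta), rownames(other))
  if (length(ms) > 0) {
    stop("site '", ms[1], "' present in '", beta_path, "' but not in '",
         other_path, "'", call. = FALSE)
  }
  ms <- setdiff(rownames(other), rownames(beta))
  if (length(ms) > 0) {
    stop("site '", ms[1], "' present in '", other_path, "' but not in '",
         beta_path, "'", call. = FALSE)
  }
  mc <- setdiff(colnames(beta), colnames(other))
  if (length(mc) > 0) {
    stop("sample '", mc[1], "' present in '", beta_path, "' but not in '",
         other_path, "'", call. = FALSE)
  }
  mc <- setdiff(colnames(other), colnames(beta))
  if (length(mc) > 0) {
    stop("sample '", mc[1], "' present in '", other_path, "' but not in '",
         beta_path, "'", call. = FALSE)
  }
  other[rownames(beta), colnames(beta), drop = FALSE]
}

#' Read a GenomeStudio-style signal export
#'
#' Expects three tab-delimited matrices in the [read_beta_matrix()] layout:
#' per-sample methylated intensities, unmethylated intensities and detection
#' p-values. Layouts are aligned by name as for [read_beta_matrix()].
#'
#' @param methylated_path,unmethylated_path Paths to the intensity matrices.
#' @param pval_path Optional detection p-value matrix path.
#' @return An object of class `signal_dataset` with elements `methylated`,
#'   `unmethylated`, `detection_p`, `site_ids`, `sample_ids`.
#' @seealso [compute_beta()]
#' @export
read_signal_matrix <- function(methylated_path, unmethylated_path,
                               pval_path = NULL) {
  m <- read_matrix_tsv(methylated_path)
  u <- read_matrix_tsv(unmethylated_path)
  u <- align_parallel_matrix(m, u, methylated_path, unmethylated_path)
  for (nm in c("methylated", "unmethylated")) {
    x <- if (nm == "methylated") m else u
    bad <- which(!is.na(x) & (x < 0 | !is.finite(x)), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("%s intensity negative or non-finite at site '%s', sample '%s'",
                   nm, rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]),
           call. = FALSE)
    }
  }
  pv <- NULL
  if (!is.null(pval_path)) {
    pv <- read_matrix_tsv(pval_path)
    pv <- align_parallel_matrix(m, pv, methylated_path, pval_path)
  } else {
    pv <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  }
  structure(list(methylated = m, unmethylated = u, detection_p = pv,
                 site_ids = rownames(m), sample_ids = colnames(m)),
            class = "signal_dataset")
}

#' Compute beta values from methylated/unmethylated signals
#'
#' The beta value is the proportion of the methylated signal among the total:
#' `beta = M / (M + U + offset)`. The offset keeps the estimate away from the
#' extremes when both signals are low (a low-intensity probe should not look
#' confidently methylated); 100 is the conventional value for Illumina
#' arrays.
#'
#' @param signals A `signal_dataset` from [read_signal_matrix()], or a list
#'   with numeric matrices `methylated` and `unmethylated` (and optionally
#'   `detection_p`) sharing dimnames.
#' @param offset Non-negative constant added to the denominator (default
#'   100).
#' @return A [beta_dataset()]; detection p-values are carried through
#'   unchanged. Cells where `M + U + offset == 0` (possible only at
#'   `offset = 0`) become missing.
#' @examples
#' sg <- list(methylated = matrix(300, 1, 1, dimnames = list("cg01", "s1")),
#'            unmethylated = matrix(100, 1, 1, dimnames = list("cg01", "s1")))
#' compute_beta(sg)$beta  # 300 / (300 + 100 + 100) = 0.6
#' @export
compute_beta <- function(signals, offset = 100) {
  if (!is.numeric(offset) || length(offset) != 1 || is.na(offset) ||
      offset < 0) {
    stop("`offset` must be a single non-negative number", call. = FALSE)
  }
  m <- signals$methylated
  u <- signals$unmethylated
  stopifnot(is.matrix(m), is.matrix(u), identical(dim(m), dim(u)))
  denom <- m + u + offset
  beta <- m / denom
  beta[!is.na(denom) & denom == 0] <- NA_real_
  pv <- signals$detection_p
  if (is.null(pv)) {
    pv <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  }
  beta_dataset(beta, pv)
}

#' Read a plain-text site-ID list
#'
#' One probe ID per line; blank lines and duplicate IDs are dropped.
#'
#' @param path Path to the list file.
#' @return Character vector of site IDs.
#' @export
read_site_list <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  unique(ids[nzchar(ids)])
}

#' Write a plain-text site-ID list
#'
#' @param ids Character vector of site IDs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}
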