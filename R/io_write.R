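# All numeric TSV output uses 6 decimal places for reproducible diffs.
fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))

dm_table_cols <- c("rank", "site_id", "score", "beta_val_dist",
                   "median_diff", "direction", "n_masked_g1", "n_masked_g2",
                   "masked_g1", "masked_g2")

#' Write a ranked differential methylation table
#'
#' One tab-delimited row per detected site, carrying the rank, score, gap,
#' median difference, direction, masked-sample information and — when an
#' annotation table is supplied — chromosome, position, gene/region pairs
#' and CpG-island relation. Sites missing from the annotation get empty
#' annotation fields and a warning.
#'
#' @param dm A `methgap_dm` object or its [tidy()] tibble.
#' @param path Output path.
#' @param ann Optional `probe_annotation` table.
#' @return `path`, invisibly.
#' @export
write_dm_table <- function(dm, path, ann = NULL) {
  rec <- if (inherits(dm, "methgap_dm")) dm$records else dm
  out <- tibble::tibble(
    rank = rec$rank,
    site_id = rec$site_id,
    score = fmt_num(rec$score),
    beta_val_dist = fmt_num(rec$beta_val_dist),
    median_diff = fmt_num(rec$median_diff),
    direction = rec$direction,
    n_masked_g1 = rec$n_masked_g1,
    n_masked_g2 = rec$n_masked_g2,
    masked_g1 = rec$masked_g1,
    masked_g2 = rec$masked_g2
  )
  if (!is.null(ann)) {
    idx <- match(rec$site_id, ann$site_id)
    if (anyNA(idx) && nrow(rec) > 0) {
      warning(sum(is.na(idx)), " site(s) not found in annotation; ",
              "annotation fields left empty")
    }
    gr <- purrr::map_chr(ann$gene_assignments, function(p) {
      if (nrow(p) == 0) "" else paste(p$gene, p$region, sep = ":",
                                      collapse = ";")
    })
    out$chromosome <- ifelse(is.na(idx), "", ann$chromosome[idx])
    out$position <- ifelse(is.na(idx), "", as.character(ann$position[idx]))
    out$gene_regions <- ifelse(is.na(idx), "", gr[idx])
    out$island_relation <- ifelse(is.na(idx), "", ann$island_relation[idx])
  }
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read a differential methylation table back into records
#'
#' Inverse of [write_dm_table()] for the record columns (annotation columns,
#' if present, are ignored); a write/read round trip reproduces the records
#' at the written precision.
#'
#' @param path Path to a TSV written by [write_dm_table()].
#' @return A tibble with the record columns of [detect_dm()]'s tidy output.
#' @export
read_dm_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    rank = readr::col_integer(),
    site_id = readr::col_character(),
    score = readr::col_double(),
    beta_val_dist = readr::col_double(),
    median_diff = readr::col_double(),
    direction = readr::col_character(),
    n_masked_g1 = readr::col_integer(),
    n_masked_g2 = readr::col_integer(),
    masked_g1 = readr::col_character(),
    masked_g2 = readr::col_character(),
    .default = readr::col_character()
  ), na = character(), progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(dm_table_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("not a differential methylation table; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- df[dm_table_cols]
  out$n_masked_total <- out$n_masked_g1 + out$n_masked_g2
  out
}

#' Write probe sequences (and optionally a gene sequence) as FASTA
#'
#' The gene's genomic DNA sequence, when given, is the first record; each
#' probe follows as one record headed by its site ID. Lines wrap at 60
#' columns. Sequences must be A/C/G/T/N strings.
#'
#' @param probes A data frame with columns `site_id` and `probe_sequence`
#'   (additional columns are appended to the FASTA headers as
#'   space-separated `key=value` fields).
#' @param path Output path.
#' @param gene_sequence Optional DNA string for the whole gene region.
#' @param gene_name Header used for the gene record (default `"gene"`).
#' @return `path`, invisibly.
#' @export
write_probe_fasta <- function(probes, path, gene_sequence = NULL,
                              gene_name = "gene") {
  seqs <- character()
  if (!is.null(gene_sequence)) {
    check_dna(gene_sequence, gene_name)
    seqs[gene_name] <- toupper(gene_sequence)
  }
  if (nrow(probes) > 0) {
    for (k in seq_len(nrow(probes))) {
      check_dna(probes$probe_sequence[k], probes$site_id[k])
    }
    hdr <- probes$site_id
    extra <- setdiff(names(probes), c("site_id", "probe_sequence"))
    if (length(extra) > 0) {
      kv <- purrr::map_chr(seq_len(nrow(probes)), function(k) {
        paste(paste0(extra, "=", unlist(probes[k, extra])), collapse = " ")
      })
      hdr <- paste(hdr, kv)
    }
    seqs[hdr] <- toupper(probes$probe_sequence)
  }
  if (length(seqs) == 0) {
    warning("no sequences to write; creating an empty FASTA file")
    file.create(path)
    return(invisible(path))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 60)
  invisible(path)
}

check_dna <- function(seq, label) {
  if (is.na(seq) || !nzchar(seq) ||
      grepl("[^ACGTNacgtn]", seq)) {
    stop("sequence for '", label, "' is not an A/C/G/T/N string",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Export detected sites as a BED track
#'
#' 0-based half-open single-base intervals; the BED score is the
#' differential methylation score scaled by 1000 and clamped to
#' `[0, 1000]`.
#'
#' @param dm A `methgap_dm` object or its tidy tibble.
#' @param ann A `probe_annotation` table providing chromosome and position.
#' @param path Output path.
#' @param chrom_prefix Prefix prepended to the manifest chromosome label
#'   (default `"chr"`; use `""` to keep labels as-is).
#' @return `path`, invisibly.
#' @export
write_dm_bed <- function(dm, ann, path, chrom_prefix = "chr") {
  rec <- if (inherits(dm, "methgap_dm")) dm$records else dm
  idx <- match(rec$site_id, ann$site_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " site(s) without annotation omitted from BED")
  }
  keep <- !is.na(idx)
  rec <- rec[keep, , drop = FALSE]
  idx <- idx[keep]
  bed <- data.frame(
    chrom = paste0(chrom_prefix, ann$chromosome[idx]),
    start = ann$position[idx] - 1L,
    end = ann$position[idx],
    name = rec$site_id,
    score = pmin(1000L, pmax(0L, as.integer(round(rec$score * 1000))))
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a beta-value (or detection p-value) matrix as TSV
#'
#' Layout matches [read_beta_matrix()]: header row of sample names, first
#' column of site IDs, 6-decimal values.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name of the first (ID) column header.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "ID_REF") {
  cols <- c(
    stats::setNames(list(rownames(m)), id_col),
    stats::setNames(lapply(seq_len(ncol(m)), function(j) fmt_num(m[, j])),
                    colnames(m))
  )
  readr::write_tsv(tibble::as_tibble(cols), path, na = "NA")
  invisible(path)
}
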