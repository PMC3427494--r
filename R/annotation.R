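# Fixed vocabularies of the Infinium manifest annotation.
region_levels <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")
island_levels <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                   "OpenSea")

manifest_required_cols <- c("IlmnID", "CHR", "MAPINFO", "UCSC_RefGene_Name",
                            "UCSC_RefGene_Group",
                            "Relation_to_UCSC_CpG_Island",
                            "Infinium_Design_Type")

#' Read an Illumina Infinium manifest CSV
#'
#' Parses the manifest CSV dialect used for the HumanMethylation450 array
#' (columns `IlmnID`, `CHR`, `MAPINFO`, `UCSC_RefGene_Name`,
#' `UCSC_RefGene_Group`, `Relation_to_UCSC_CpG_Island`,
#' `Infinium_Design_Type`, optionally `AlleleA_ProbeSeq`). Preamble lines
#' before the column-header line and a trailing `[Controls]` section are
#' tolerated.
#'
#' The semicolon-delimited `UCSC_RefGene_Name` and `UCSC_RefGene_Group`
#' columns are split positionally into parallel (gene, region) pairs and
#' deduplicated. An empty CpG-island relation maps to `OpenSea` (the probe
#' lies in none of the island/shore/shelf zones).
#'
#' @param path Path to the manifest CSV.
#' @return A tibble of class `probe_annotation` with one row per site:
#'   `site_id`, `chromosome` (label such as `"1"`..`"22"`, `"X"`, `"Y"`),
#'   `position` (1-based), `gene_assignments` (list column of tibbles with
#'   columns `gene`, `region`), `island_relation`, `design_type`,
#'   `probe_sequence` (`NA` when the column is absent).
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\"?IlmnID\"?,", lines)[1]
  if (is.na(hdr)) {
    stop("no header line starting with 'IlmnID' found in '", path, "'",
         call. = FALSE)
  }
  ctrl <- grep("^\\[Controls\\]", lines)
  ctrl <- ctrl[ctrl > hdr][1]
  end <- if (is.na(ctrl)) length(lines) else ctrl - 1L
  df <- utils::read.csv(text = paste(lines[hdr:end], collapse = "\n"),
                        stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(manifest_required_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("manifest is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pairs <- purrr::map2(df$UCSC_RefGene_Name, df$UCSC_RefGene_Group,
                       split_gene_regions)
  bad <- which(purrr::map_lgl(pairs, is.null))
  if (length(bad) > 0) {
    stop("gene and region lists have unequal lengths at site '",
         df$IlmnID[bad[1]], "'", call. = FALSE)
  }
  island <- df$Relation_to_UCSC_CpG_Island
  island[is.na(island) | !nzchar(island)] <- "OpenSea"
  unknown <- setdiff(unique(island), island_levels)
  if (length(unknown) > 0) {
    stop("unknown CpG-island relation label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ann <- tibble::tibble(
    site_id = df$IlmnID,
    chromosome = df$CHR,
    position = as.integer(df$MAPINFO),
    gene_assignments = pairs,
    island_relation = island,
    design_type = df$Infinium_Design_Type,
    probe_sequence = if ("AlleleA_ProbeSeq" %in% names(df)) {
      seq <- df$AlleleA_ProbeSeq
      seq[!nzchar(seq)] <- NA_character_
      seq
    } else NA_character_
  )
  class(ann) <- c("probe_annotation", class(ann))
  ann
}

# Zip semicolon lists positionally; NULL signals unequal lengths.
split_gene_regions <- function(genes, regions) {
  if (is.na(genes) || !nzchar(genes)) {
    return(tibble::tibble(gene = character(), region = character()))
  }
  g <- strsplit(genes, ";", fixed = TRUE)[[1]]
  r <- if (is.na(regions)) character() else
    strsplit(regions, ";", fixed = TRUE)[[1]]
  if (length(g) != length(r)) return(NULL)
  unknown <- setdiff(unique(r), region_levels)
  if (length(unknown) > 0) {
    stop("unknown gene-region label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dplyr::distinct(tibble::tibble(gene = g, region = r))
}

#' Long-form (site, gene, region) pairs of an annotation table
#'
#' @param ann A `probe_annotation` tibble from [read_manifest()] or
#'   [simulate_methylation()].
#' @return A tibble with columns `site_id`, `gene`, `region`, one row per
#'   deduplicated (site, gene, region) triple; sites with no gene assignment
#'   contribute no rows.
#' @export
gene_region_pairs <- function(ann) {
  keep <- purrr::map_int(ann$gene_assignments, nrow) > 0
  if (!any(keep)) {
    return(tibble::tibble(site_id = character(), gene = character(),
                          region = character()))
  }
  tidyr::unnest(
    tibble::tibble(site_id = ann$site_id[keep],
                   gene_assignments = ann$gene_assignments[keep]),
    "gene_assignments"
  )
}

#' Serialise a probe annotation table to CSV
#'
#' Writes the manifest-dialect columns so that [read_manifest()] on the
#' output reproduces the table (parsing is idempotent).
#'
#' @param ann A `probe_annotation` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(ann, path) {
  df <- data.frame(
    IlmnID = ann$site_id,
    CHR = ann$chromosome,
    MAPINFO = ann$position,
    UCSC_RefGene_Name = purrr::map_chr(
      ann$gene_assignments, ~ paste(.x$gene, collapse = ";")),
    UCSC_RefGene_Group = purrr::map_chr(
      ann$gene_assignments, ~ paste(.x$region, collapse = ";")),
    Relation_to_UCSC_CpG_Island = ifelse(ann$island_relation == "OpenSea",
                                         "", ann$island_relation),
    Infinium_Design_Type = ann$design_type,
    AlleleA_ProbeSeq = ifelse(is.na(ann$probe_sequence), "",
                              ann$probe_sequence),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
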