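# TSV writers for the two result tables. Row order is deterministic
# (sorted by chromosome, position and identifiers); missing fields are
# written as empty strings.

PAIRS_TSV_COLS <- c("population", "snp1_id", "chrom1", "pos1",
                    "snp2_id", "chrom2", "pos2", "r2", "d_prime", "d",
                    "n_haplotypes", "separation",
                    "gene1", "feature1", "coding_effect1",
                    "gene2", "feature2", "coding_effect2")

INTERACTIONS_TSV_COLS <- c("gene1", "gene2", "category", "coding_subtype",
                           "population", "support_count",
                           "supporting_snp_pairs", "known_evidence")

#' Write long-range LD pairs as TSV
#'
#' One row per (pair x annotation combination): a SNP annotated to several
#' genes or features yields one row per placement. Plain (unannotated)
#' pair tables are written with empty annotation columns.
#'
#' @param pairs Pair tibble from [scan_panels()] or [annotate_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  out <- as_tibble(pairs)
  for (col in PAIRS_TSV_COLS) {
    if (!col %in% names(out)) out[[col]] <- NA_character_
  }
  out <- out[, PAIRS_TSV_COLS]
  out <- dplyr::arrange(out, .data$population, .data$chrom1, .data$pos1,
                        .data$chrom2, .data$pos2, .data$snp1_id,
                        .data$snp2_id, .data$gene1, .data$gene2,
                        .data$feature1, .data$feature2)
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write gene interactions as TSV
#'
#' One row per (gene pair x category x coding subtype x population), with
#' support counts and supporting SNP-pair lists.
#'
#' @param ldgis Interaction tibble from [build_interactions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions_tsv <- function(ldgis, path) {
  out <- as_tibble(ldgis)
  if (!"known_evidence" %in% names(out)) out$known_evidence <- ""
  out <- out[, INTERACTIONS_TSV_COLS]
  out <- dplyr::arrange(out, .data$gene1, .data$gene2, .data$category,
                        .data$coding_subtype, .data$population)
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}
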