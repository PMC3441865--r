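# Feature annotation: place SNPs in promoter/UTR/CDS features of gene
# models and classify coding substitutions as synonymous/nonsynonymous.

#' Promoter interval of a gene
#'
#' The promoter is the 2 kb immediately upstream of the gene-level TSS,
#' strand aware and half-open so it never overlaps the transcript itself:
#' `[tss - 2000, tss)` on the plus strand, `[tss + 1, tss + 2001)` on the
#' minus strand, clamped at chromosome bounds.
#'
#' @param gene One-row data frame or list with `tss`, `strand`, `chrom`.
#' @param chrom_length Optional chromosome length for right-clamping.
#' @return A list with `start` and `end` (0-based half-open).
#' @export
promoter_interval <- function(gene, chrom_length = NULL) {
  if (gene$strand == "+") {
    start <- max(0L, gene$tss - 2000L)
    end <- gene$tss
  } else {
    start <- gene$tss + 1L
    end <- gene$tss + 2001L
    if (!is.null(chrom_length)) end <- min(end, chrom_length)
  }
  list(start = as.integer(start), end = as.integer(end))
}

#' Annotate one SNP against gene models
#'
#' Reports every placement of the SNP position across genes and
#' transcripts: a `PROMOTER` row per gene whose promoter contains it, and
#' per transcript either a `CDS` row (with the synonymous/nonsynonymous
#' call for codable transcripts) or a `UTR` row (5' or 3', strand aware)
#' for exonic positions outside the CDS. Within one transcript CDS takes
#' precedence over UTR; across overlapping transcripts and genes all
#' placements are reported, so one SNP can yield several rows. Intergenic
#' SNPs yield zero rows and are thereby excluded from gene interactions.
#'
#' @param snp One-row data frame or list with `snp_id`, `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param models A [gene_models] object (genome attached if coding-effect
#'   calls are wanted).
#' @return A tibble with columns `snp_id`, `gene_id`, `gene_name`,
#'   `transcript_id`, `feature`, `utr_side`, `coding_effect`.
#' @export
annotate_snp <- function(snp, models) {
  rows <- list()
  genes <- models$genes[models$genes$chrom == snp$chrom, ]
  chrom_len <- if (!is.null(models$genome) && snp$chrom %in% names(models$genome)) {
    length(models$genome[[snp$chrom]])
  } else NULL

  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    pr <- promoter_interval(g, chrom_len)
    if (snp$pos >= pr$start && snp$pos < pr$end) {
      rows[[length(rows) + 1L]] <- tibble(
        snp_id = snp$snp_id, gene_id = g$gene_id, gene_name = g$gene_name,
        transcript_id = NA_character_, feature = "PROMOTER",
        utr_side = NA_integer_, coding_effect = NA_character_
      )
    }
    txs <- models$transcripts[models$transcripts$gene_id == g$gene_id, ]
    for (ti in seq_len(nrow(txs))) {
      tx <- txs[ti, ]
      seg <- models$cds[models$cds$transcript_id == tx$transcript_id, ]
      if (nrow(seg) == 0L) next  # non-coding transcript: no UTR/CDS call
      in_cds <- any(snp$pos >= seg$start & snp$pos < seg$end)
      if (in_cds) {
        eff <- if (isTRUE(tx$codable) && !is.null(models$genome)) {
          coding_effect(snp, models, tx$transcript_id)
        } else NA_character_
        rows[[length(rows) + 1L]] <- tibble(
          snp_id = snp$snp_id, gene_id = g$gene_id, gene_name = g$gene_name,
          transcript_id = tx$transcript_id, feature = "CDS",
          utr_side = NA_integer_, coding_effect = eff
        )
        next
      }
      ex <- models$exons[models$exons$transcript_id == tx$transcript_id, ]
      in_exon <- any(snp$pos >= ex$start & snp$pos < ex$end)
      if (in_exon) {
        cds_lo <- min(seg$start)
        cds_hi <- max(seg$end)
        side <- if (g$strand == "+") {
          if (snp$pos < cds_lo) 5L else 3L
        } else {
          if (snp$pos >= cds_hi) 5L else 3L
        }
        rows[[length(rows) + 1L]] <- tibble(
          snp_id = snp$snp_id, gene_id = g$gene_id, gene_name = g$gene_name,
          transcript_id = tx$transcript_id, feature = "UTR",
          utr_side = side, coding_effect = NA_character_
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(snp_id = character(), gene_id = character(),
                  gene_name = character(), transcript_id = character(),
                  feature = character(), utr_side = integer(),
                  coding_effect = character()))
  }
  dplyr::bind_rows(rows)
}

#' Annotate a SNP table against gene models
#'
#' @param snps Tibble with `snp_id`, `chrom`, `pos`, `ref`, `alt` (e.g.
#'   `panel$snps`).
#' @param models A [gene_models] object.
#' @return Row-bound [annotate_snp()] results for all SNPs, sorted by
#'   `snp_id`, `gene_id`, `transcript_id`, `feature`.
#' @export
annotate_snps <- function(snps, models) {
  out <- dplyr::bind_rows(
    lapply(seq_len(nrow(snps)), function(i) annotate_snp(snps[i, ], models))
  )
  if (nrow(out) == 0L) {
    return(tibble(snp_id = character(), gene_id = character(),
                  gene_name = character(), transcript_id = character(),
                  feature = character(), utr_side = integer(),
                  coding_effect = character()))
  }
  dplyr::arrange(out, .data$snp_id, .data$gene_id, .data$transcript_id,
                 .data$feature)
}

#' Synonymous/nonsynonymous call for a coding SNP
#'
#' Locates the SNP's CDS-relative offset by summing spliced CDS segments
#' in strand order (on the minus strand the complement of each genomic
#' allele is used), substitutes ref -> alt in the containing codon, and
#' translates both codons with the standard genetic code. Equal amino
#' acids give `"SYNONYMOUS"`; anything else — including stop gain/loss,
#' since the stop signal is treated as a distinct residue —
#' `"NONSYNONYMOUS"`.
#'
#' @param snp One-row data frame or list with `chrom`, `pos`, `ref`,
#'   `alt`, `snp_id`.
#' @param models A [gene_models] object with genome attached.
#' @param transcript_id Codable transcript whose CDS contains the SNP.
#' @return `"SYNONYMOUS"` or `"NONSYNONYMOUS"`.
#' @export
coding_effect <- function(snp, models, transcript_id) {
  tx <- models$transcripts[models$transcripts$transcript_id == transcript_id, ]
  stopifnot(nrow(tx) == 1L, isTRUE(tx$codable))
  seg <- models$cds[models$cds$transcript_id == transcript_id, ]
  strand <- tx$strand

  genome_base <- as.character(Biostrings::subseq(models$genome[[snp$chrom]],
                                                 start = snp$pos + 1L,
                                                 width = 1L))
  if (genome_base != snp$ref) {
    stop("REF_MISMATCH: SNP ", snp$snp_id, " ref allele ", snp$ref,
         " disagrees with genome base ", genome_base, " at ", snp$chrom,
         ":", snp$pos, call. = FALSE)
  }

  hit <- which(snp$pos >= seg$start & snp$pos < seg$end)
  if (length(hit) != 1L) {
    stop("SNP ", snp$snp_id, " is not inside the CDS of ", transcript_id,
         call. = FALSE)
  }
  if (strand == "+") {
    before <- sum(pmax(0L, seg$end[seq_len(nrow(seg)) < hit] -
                         seg$start[seq_len(nrow(seg)) < hit]))
    offset <- before + (snp$pos - seg$start[[hit]])
    ref_c <- snp$ref
    alt_c <- snp$alt
  } else {
    after <- sum(pmax(0L, seg$end[seq_len(nrow(seg)) > hit] -
                        seg$start[seq_len(nrow(seg)) > hit]))
    offset <- after + (seg$end[[hit]] - 1L - snp$pos)
    alpha <- c(A = "T", C = "G", G = "C", T = "A")
    ref_c <- alpha[[snp$ref]]
    alt_c <- alpha[[snp$alt]]
  }

  cds_seq <- models$cds_seq[[transcript_id]]
  if (substr(cds_seq, offset + 1L, offset + 1L) != ref_c) {
    stop("REF_MISMATCH: SNP ", snp$snp_id, " strand-adjusted ref ", ref_c,
         " disagrees with CDS sequence of ", transcript_id, call. = FALSE)
  }
  codon_start <- (offset %/% 3L) * 3L
  codon <- substr(cds_seq, codon_start + 1L, codon_start + 3L)
  within <- offset - codon_start
  alt_codon <- codon
  substr(alt_codon, within + 1L, within + 1L) <- alt_c

  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (aa_ref == aa_alt) "SYNONYMOUS" else "NONSYNONYMOUS"
}
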