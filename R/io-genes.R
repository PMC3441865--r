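# Gene models: strand-aware gene/transcript geometry plus spliced CDS
# sequence, backed by GFF3 + genome FASTA. All internal coordinates are
# 0-based half-open; GFF3's 1-based closed intervals are converted at the
# boundary.

#' Construct a gene-models object
#'
#' Assembles gene/transcript/exon/CDS tables into one annotation object.
#' The TSS of each gene is derived as the 5'-most exon boundary (strand
#' aware) across its transcripts. When a genome is supplied, each
#' transcript's spliced CDS sequence is extracted in reading-frame order
#' (minus-strand CDS reverse-complemented); transcripts whose total CDS
#' length is not divisible by 3 are flagged non-codable (their UTR/CDS
#' intervals remain usable, coding-effect calls are skipped) with a
#' warning.
#'
#' @param genes Tibble: `gene_id`, `gene_name`, `chrom`, `strand`.
#' @param transcripts Tibble: `transcript_id`, `gene_id`.
#' @param exons,cds Tibbles: `transcript_id`, `start`, `end` (0-based
#'   half-open).
#' @param genome Optional named `Biostrings::DNAStringSet` keyed by
#'   chromosome.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, transcripts, exons, cds, genome = NULL) {
  genes <- as_tibble(genes)
  transcripts <- as_tibble(transcripts)
  exons <- dplyr::arrange(as_tibble(exons), .data$transcript_id, .data$start)
  cds <- dplyr::arrange(as_tibble(cds), .data$transcript_id, .data$start)
  stopifnot(all(genes$strand %in% c("+", "-")))

  transcripts <- dplyr::left_join(
    transcripts,
    dplyr::select(genes, "gene_id", "chrom", "strand"),
    by = "gene_id"
  )

  # gene TSS: 5'-most exon boundary over the gene's transcripts
  ex_tx <- dplyr::left_join(exons,
                            dplyr::select(transcripts, "transcript_id",
                                          "gene_id"),
                            by = "transcript_id")
  span <- if (nrow(ex_tx) == 0L) {
    tibble(gene_id = character(), lo = integer(), hi = integer())
  } else {
    dplyr::summarise(dplyr::group_by(ex_tx, .data$gene_id),
                     lo = min(.data$start), hi = max(.data$end),
                     .groups = "drop")
  }
  genes <- dplyr::left_join(genes, span, by = "gene_id")
  genes$tss <- ifelse(genes$strand == "+", genes$lo, genes$hi - 1L)
  genes <- dplyr::rename(genes, start = "lo", end = "hi")

  cds_len <- dplyr::summarise(dplyr::group_by(cds, .data$transcript_id),
                              len = sum(.data$end - .data$start),
                              .groups = "drop")
  transcripts <- dplyr::left_join(transcripts, cds_len, by = "transcript_id")
  transcripts$len[is.na(transcripts$len)] <- 0L
  transcripts$codable <- transcripts$len > 0L & transcripts$len %% 3L == 0L
  bad <- transcripts$transcript_id[transcripts$len > 0L & !transcripts$codable]
  if (length(bad) > 0L) {
    warning("CDS length not divisible by 3; transcript(s) flagged non-codable: ",
            paste(bad, collapse = ", "), call. = FALSE)
  }

  cds_seq <- character(0)
  if (!is.null(genome)) {
    codable_tx <- transcripts$transcript_id[transcripts$codable]
    cds_seq <- vapply(codable_tx, function(tx) {
      seg <- cds[cds$transcript_id == tx, ]
      strand <- transcripts$strand[transcripts$transcript_id == tx][[1L]]
      chrom <- transcripts$chrom[transcripts$transcript_id == tx][[1L]]
      pieces <- vapply(seq_len(nrow(seg)), function(i) {
        as.character(Biostrings::subseq(genome[[chrom]],
                                        start = seg$start[[i]] + 1L,
                                        end = seg$end[[i]]))
      }, character(1L))
      s <- paste(pieces, collapse = "")
      if (strand == "-") {
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      }
      s
    }, character(1L))
    names(cds_seq) <- codable_tx
  }

  structure(
    list(genes = genes,
         transcripts = dplyr::select(transcripts, -"len"),
         exons = exons, cds = cds,
         cds_seq = cds_seq, genome = genome),
    class = "gene_models"
  )
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d gene(s), %d transcript(s), %d exon(s), %d CDS segment(s)%s\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons), nrow(x$cds),
              if (is.null(x$genome)) "" else
                sprintf("; genome: %d sequence(s)", length(x$genome))))
  invisible(x)
}

#' Read gene models from GFF3 + genome FASTA
#'
#' Expects `gene`, `mRNA` (or `transcript`), `exon` and `CDS` features
#' linked by `ID`/`Parent` attributes. GFF3 1-based closed coordinates are
#' converted to the internal 0-based half-open convention; minus-strand
#' CDS sequence is reverse-complemented into reading-frame order.
#'
#' @param gff3_path Path to a GFF3 file.
#' @param fasta_path Path to the genome FASTA covering the referenced
#'   chromosomes.
#' @return A [gene_models] object (with the genome attached).
#' @export
read_gene_models <- function(gff3_path, fasta_path) {
  gr <- rtracklayer::import(gff3_path)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # GFF3 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (is.null(gr$ID)) NA_character_ else as.character(gr$ID),
    name = if (is.null(gr$Name)) NA_character_ else as.character(gr$Name),
    parent = vapply(
      if (is.null(gr$Parent)) replicate(length(gr), character(0), simplify = FALSE)
      else as.list(gr$Parent),
      function(p) if (length(p) == 0L) NA_character_ else p[[1L]],
      character(1L))
  )

  g <- df[df$type == "gene", ]
  genes <- tibble(
    gene_id = g$id,
    gene_name = ifelse(is.na(g$name), g$id, g$name),
    chrom = g$chrom,
    strand = g$strand
  )
  tx <- df[df$type %in% c("mRNA", "transcript"), ]
  transcripts <- tibble(transcript_id = tx$id, gene_id = tx$parent)
  ex <- df[df$type == "exon", ]
  exons <- tibble(transcript_id = ex$parent, start = ex$start, end = ex$end)
  cd <- df[df$type == "CDS", ]
  cds <- tibble(transcript_id = cd$parent, start = cd$start, end = cd$end)

  gene_models(genes, transcripts, exons, cds, genome = genome)
}

#' Write gene models as GFF3 (plus optional genome FASTA)
#'
#' @param models A [gene_models] object.
#' @param gff3_path Output GFF3 path.
#' @param fasta_path Optional output FASTA path for the attached genome.
#' @return `gff3_path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, gff3_path, fasta_path = NULL) {
  row9 <- function(chrom, src, type, start0, end0, strand, attrs) {
    paste(chrom, src, type, start0 + 1L, end0, ".", strand, ".", attrs,
          sep = "\t")
  }
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    lines <- c(lines, row9(g$chrom, "ldgi", "gene", g$start, g$end, g$strand,
                           sprintf("ID=%s;Name=%s", g$gene_id, g$gene_name)))
    txs <- models$transcripts[models$transcripts$gene_id == g$gene_id, ]
    for (j in seq_len(nrow(txs))) {
      tx <- txs[j, ]
      tex <- models$exons[models$exons$transcript_id == tx$transcript_id, ]
      tcd <- models$cds[models$cds$transcript_id == tx$transcript_id, ]
      lines <- c(lines,
                 row9(g$chrom, "ldgi", "mRNA", min(tex$start), max(tex$end),
                      g$strand, sprintf("ID=%s;Parent=%s", tx$transcript_id,
                                        g$gene_id)))
      for (k in seq_len(nrow(tex))) {
        lines <- c(lines, row9(g$chrom, "ldgi", "exon", tex$start[[k]],
                               tex$end[[k]], g$strand,
                               sprintf("Parent=%s", tx$transcript_id)))
      }
      for (k in seq_len(nrow(tcd))) {
        lines <- c(lines, row9(g$chrom, "ldgi", "CDS", tcd$start[[k]],
                               tcd$end[[k]], g$strand,
                               sprintf("Parent=%s", tx$transcript_id)))
      }
    }
  }
  writeLines(lines, gff3_path)
  if (!is.null(fasta_path) && !is.null(models$genome)) {
    Biostrings::writeXStringSet(models$genome, fasta_path, width = 80L)
  }
  invisible(gff3_path)
}
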