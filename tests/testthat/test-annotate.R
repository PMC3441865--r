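# SNP-to-feature placement and synonymous/nonsynonymous classification.

test_that("promoter intervals are the strand-aware 2 kb immediately upstream", {
  plus <- promoter_interval(list(tss = 10000L, strand = "+", chrom = "c"))
  expect_equal(c(plus$start, plus$end), c(8000L, 10000L))
  expect_equal(plus$end - plus$start, 2000L)

  minus <- promoter_interval(list(tss = 5000L, strand = "-", chrom = "c"))
  expect_equal(c(minus$start, minus$end), c(5001L, 7001L))
  expect_equal(minus$end - minus$start, 2000L)

  clamped <- promoter_interval(list(tss = 1500L, strand = "+", chrom = "c"))
  expect_equal(c(clamped$start, clamped$end), c(0L, 1500L))

  rclamped <- promoter_interval(list(tss = 5000L, strand = "-", chrom = "c"),
                                chrom_length = 6000L)
  expect_equal(rclamped$end, 6000L)
})

test_that("coding effect translates designed codons on the plus strand", {
  # chromosome spelling CAT AAA TAC from position 10, CDS = [10, 19)
  seq <- paste0(strrep("G", 10), "CATAAATAC", strrep("G", 10))
  mod <- toy_gene_models(seq, cbind(5L, 25L), cbind(10L, 19L), "+")

  his_arg <- list(snp_id = "x", chrom = "chrT", pos = 11L, ref = "A",
                  alt = "G")  # CAT -> CGT
  expect_equal(coding_effect(his_arg, mod, "G1.t1"), "NONSYNONYMOUS")

  lys_lys <- list(snp_id = "x", chrom = "chrT", pos = 15L, ref = "A",
                  alt = "G")  # AAA -> AAG
  expect_equal(coding_effect(lys_lys, mod, "G1.t1"), "SYNONYMOUS")

  stop_gain <- list(snp_id = "x", chrom = "chrT", pos = 18L, ref = "C",
                    alt = "A")  # TAC -> TAA: stop counts as a change
  expect_equal(coding_effect(stop_gain, mod, "G1.t1"), "NONSYNONYMOUS")

  mismatch <- list(snp_id = "bad", chrom = "chrT", pos = 11L, ref = "T",
                   alt = "G")
  expect_error(coding_effect(mismatch, mod, "G1.t1"), "REF_MISMATCH.*bad")
})

test_that("coding effect handles a spliced minus-strand transcript", {
  # two-exon minus-strand gene; CDS read right to left across the intron.
  # reading-frame CDS designed as CTC CTC (Leu Leu): genomic = revcomp
  # placed into segments [30,33) (offsets 3..5) and [40,43) (offsets 0..2)
  cds_rf <- "CTCCTC"
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  seq <- paste0(strrep("A", 30), rc(substr(cds_rf, 4, 6)),
                strrep("A", 7), rc(substr(cds_rf, 1, 3)), strrep("A", 17))
  mod <- toy_gene_models(seq, rbind(c(28L, 34L), c(38L, 44L)),
                         rbind(c(30L, 33L), c(40L, 43L)), "-")
  expect_equal(unname(mod$cds_seq["G1.t1"]), cds_rf)

  # CDS offset 2 is genomic position 40 (start of the right segment);
  # codon CTC -> CTT via genomic G -> A (complement C -> T): Leu, silent
  syn <- list(snp_id = "m", chrom = "chrT", pos = 40L,
              ref = substr(seq, 41, 41), alt = "A")
  expect_equal(substr(seq, 41, 41), "G")
  expect_equal(coding_effect(syn, mod, "G1.t1"), "SYNONYMOUS")

  # CDS offset 4 (middle of second codon) genomic position 31:
  # CTC -> CAC via complement T -> A (genomic A -> T): Leu -> His
  nonsyn <- list(snp_id = "m", chrom = "chrT", pos = 31L,
                 ref = substr(seq, 32, 32), alt = "T")
  expect_equal(coding_effect(nonsyn, mod, "G1.t1"), "NONSYNONYMOUS")
})

test_that("stop-affecting substitutions are nonsynonymous in a spot-check of degenerate and stop codons", {
  # representative codons: 4-fold degenerate (CTx), 2-fold (AAx), stop
  cases <- list(
    list(codon = "CTG", pos = 2L, alt = "A", expected = "SYNONYMOUS"),
    list(codon = "AAA", pos = 2L, alt = "G", expected = "SYNONYMOUS"),
    list(codon = "AAA", pos = 2L, alt = "C", expected = "NONSYNONYMOUS"),
    list(codon = "TAC", pos = 2L, alt = "A", expected = "NONSYNONYMOUS"),
    list(codon = "TAA", pos = 0L, alt = "C", expected = "NONSYNONYMOUS"))
  for (cs in cases) {
    seq_p <- paste0(strrep("A", 10), cs$codon, strrep("A", 10))
    mod_p <- toy_gene_models(seq_p, cbind(8L, 16L), cbind(10L, 13L), "+")
    ref <- substr(cs$codon, cs$pos + 1L, cs$pos + 1L)
    snp <- list(snp_id = "s", chrom = "chrT", pos = 10L + cs$pos,
                ref = ref, alt = cs$alt)
    expect_equal(coding_effect(snp, mod_p, "G1.t1"), cs$expected,
                 label = paste(cs$codon, cs$pos, cs$alt))
    # oracle agreement on the same case
    alt_codon <- cs$codon
    substr(alt_codon, cs$pos + 1L, cs$pos + 1L) <- cs$alt
    oracle <- if (identical(codon_aa(cs$codon), codon_aa(alt_codon))) {
      "SYNONYMOUS"
    } else "NONSYNONYMOUS"
    expect_equal(oracle, cs$expected)
  }
})

test_that("annotate_snp reports every placement across overlapping genes and transcripts", {
  # gene G1 (+): exon [10, 40), CDS [13, 31); gene G2 (+): exon [20, 50),
  # CDS [20, 26) -> positions 26..49 of G2 are 3' UTR
  seq <- paste(rep("ACGT", 20), collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(seq, "chrT"))
  mod <- gene_models(
    genes = tibble::tibble(gene_id = c("G1", "G2"),
                           gene_name = c("G1", "G2"),
                           chrom = "chrT", strand = "+"),
    transcripts = tibble::tibble(transcript_id = c("G1.t1", "G2.t1"),
                                 gene_id = c("G1", "G2")),
    exons = tibble::tibble(transcript_id = c("G1.t1", "G2.t1"),
                           start = c(10L, 20L), end = c(40L, 50L)),
    cds = tibble::tibble(transcript_id = c("G1.t1", "G2.t1"),
                         start = c(13L, 20L), end = c(31L, 26L)),
    genome = genome
  )

  shared <- list(snp_id = "s", chrom = "chrT", pos = 28L,
                 ref = substr(seq, 29, 29),
                 alt = setdiff(c("A", "C", "G", "T"),
                               substr(seq, 29, 29))[[1]])
  ann <- annotate_snp(shared, mod)
  expect_equal(nrow(ann), 2L)
  expect_setequal(ann$feature, c("CDS", "UTR"))
  expect_equal(ann$utr_side[ann$feature == "UTR"], 3L)
  expect_false(is.na(ann$coding_effect[ann$feature == "CDS"]))

  # 5' UTR of G1; the same position is upstream of G2's TSS, so a
  # promoter placement for G2 is reported alongside
  utr5 <- list(snp_id = "u", chrom = "chrT", pos = 11L, ref = "G", alt = "A")
  a5 <- annotate_snp(utr5, mod)
  expect_equal(a5$feature[a5$gene_id == "G1"], "UTR")
  expect_equal(a5$utr_side[a5$gene_id == "G1"], 5L)
  expect_equal(a5$feature[a5$gene_id == "G2"], "PROMOTER")

  # promoter-only SNP: upstream of G1's TSS, transcript field empty
  prom <- list(snp_id = "p", chrom = "chrT", pos = 5L, ref = "C", alt = "T")
  ap <- annotate_snp(prom, mod)
  expect_setequal(ap$feature, "PROMOTER")
  expect_true(all(is.na(ap$transcript_id)))

  # intergenic SNP: no rows
  inter <- list(snp_id = "i", chrom = "chrT", pos = 70L, ref = "G",
                alt = "A")
  expect_equal(nrow(annotate_snp(inter, mod)), 0L)
})

test_that("within one transcript an exonic position is CDS or UTR, never both", {
  b <- simulate_gene_landscape(sim_config(n_cross_pairs = 8L,
                                          n_background_per_chrom = 0L),
                               seed = 9)
  ann <- annotate_snps(b$snps, b$models)
  exonic <- ann[!is.na(ann$transcript_id), ]
  dup <- dplyr::count(exonic, .data$snp_id, .data$transcript_id)
  expect_true(all(dup$n == 1L))
})

test_that("simulated landscapes realize their prescribed placements", {
  b <- simulate_gene_landscape(sim_config(), seed = 13)
  ann <- annotate_snps(b$snps, b$models)
  got <- dplyr::arrange(
    dplyr::distinct(dplyr::select(ann, "snp_id", "gene_id", "feature",
                                  "utr_side", "coding_effect")),
    .data$snp_id, .data$gene_id)
  want <- dplyr::arrange(b$placements, .data$snp_id, .data$gene_id)
  expect_equal(as.data.frame(got), as.data.frame(want))
})
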