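# Categorization, aggregation and evidence overlay of gene interactions.

mk_pair <- function(s1 = "s1", s2 = "s2", pop = "P1") {
  tibble::tibble(
    population = pop, snp1_id = s1, chrom1 = "chr1", pos1 = 10L,
    snp2_id = s2, chrom2 = "chr2", pos2 = 20L, r2 = 0.95, d_prime = 1,
    d = 0.2, n_haplotypes = 40L, separation = "DIFF_CHROM")
}

mk_ann <- function(snp_id, gene_id, feature, effect = NA_character_,
                   side = NA_integer_) {
  tibble::tibble(snp_id = snp_id, gene_id = gene_id, gene_name = gene_id,
                 transcript_id = ifelse(feature == "PROMOTER",
                                        NA_character_,
                                        paste0(gene_id, ".t1")),
                 feature = feature, utr_side = side, coding_effect = effect)
}

test_that("feature pairs map onto the six categories in canonical order with CDS subtypes", {
  ct <- categorize_pair("PROMOTER", "CDS", NA, "NONSYNONYMOUS")
  expect_equal(ct$category, "PROMOTER-CDS")
  expect_equal(ct$coding_subtype, "NONSYN-NA")

  # order of arguments never matters
  ct2 <- categorize_pair("CDS", "PROMOTER", "NONSYNONYMOUS", NA)
  expect_equal(ct2, ct)

  cc <- categorize_pair("CDS", "CDS", "SYNONYMOUS", "NONSYNONYMOUS")
  expect_equal(cc$category, "CDS-CDS")
  expect_equal(cc$coding_subtype, "NONSYN-SYN")

  uu <- categorize_pair("UTR", "UTR")
  expect_equal(uu$category, "UTR-UTR")
  expect_true(is.na(uu$coding_subtype))

  cu <- categorize_pair("UTR", "CDS", NA, "SYNONYMOUS")
  expect_equal(cu$category, "CDS-UTR")
  expect_equal(cu$coding_subtype, "SYN-NA")

  # exhaustive closure: every combination lands in the six-way set
  feats <- c("PROMOTER", "CDS", "UTR")
  for (f1 in feats) for (f2 in feats) {
    expect_true(categorize_pair(f1, f2, "SYNONYMOUS", "SYNONYMOUS")$category
                %in% c("PROMOTER-PROMOTER", "PROMOTER-CDS", "PROMOTER-UTR",
                       "CDS-CDS", "CDS-UTR", "UTR-UTR"))
  }
})

test_that("interactions accrue per annotation combination, drop self-pairs, and aggregate with support counts", {
  pairs <- mk_pair()
  ann <- dplyr::bind_rows(
    mk_ann("s1", "GA", "PROMOTER"),
    mk_ann("s2", "GB", "CDS", "SYNONYMOUS"),
    mk_ann("s2", "GC", "UTR", side = 3L))
  ldgis <- build_interactions(annotate_pairs(pairs, ann))
  expect_equal(nrow(ldgis), 2L)
  expect_setequal(ldgis$category, c("PROMOTER-CDS", "PROMOTER-UTR"))
  expect_setequal(paste(ldgis$gene1, ldgis$gene2), c("GA GB", "GA GC"))

  # both SNPs in the same gene: no interaction, counted
  self_ann <- dplyr::bind_rows(mk_ann("s1", "GA", "CDS", "SYNONYMOUS"),
                               mk_ann("s2", "GA", "UTR", side = 3L))
  selfed <- build_interactions(annotate_pairs(pairs, self_ann))
  expect_equal(nrow(selfed), 0L)
  expect_equal(attr(selfed, "self_pairs"), 1L)

  # two pairs supporting the same gene pair and category aggregate
  pairs2 <- dplyr::bind_rows(mk_pair("s1", "s2"), mk_pair("s3", "s4"))
  ann2 <- dplyr::bind_rows(
    mk_ann("s1", "GA", "PROMOTER"), mk_ann("s2", "GB", "UTR", side = 5L),
    mk_ann("s3", "GA", "PROMOTER"), mk_ann("s4", "GB", "UTR", side = 3L))
  agg <- build_interactions(annotate_pairs(pairs2, ann2))
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$support_count, 2L)
  expect_equal(agg$supporting_snp_pairs, "s1|s2;s3|s4")

  # count law: aggregated LDGIs never exceed the annotation cross product
  expect_lte(nrow(ldgis), 1L * 3L)
})

test_that("the interaction set is invariant under swapping the SNPs within pairs", {
  pairs <- dplyr::bind_rows(mk_pair("s1", "s2"), mk_pair("s3", "s4"))
  ann <- dplyr::bind_rows(
    mk_ann("s1", "GA", "CDS", "NONSYNONYMOUS"),
    mk_ann("s2", "GB", "CDS", "SYNONYMOUS"),
    mk_ann("s3", "GB", "PROMOTER"),
    mk_ann("s4", "GC", "UTR", side = 3L))
  fwd <- build_interactions(annotate_pairs(pairs, ann))
  swapped <- dplyr::rename(pairs,
                           snp1_id = "snp2_id", chrom1 = "chrom2",
                           pos1 = "pos2", snp2_id = "snp1_id",
                           chrom2 = "chrom1", pos2 = "pos1")
  rev <- build_interactions(annotate_pairs(swapped, ann))
  cols <- c("gene1", "gene2", "category", "coding_subtype", "population",
            "support_count")
  expect_equal(as.data.frame(fwd[, cols]), as.data.frame(rev[, cols]))
})

test_that("evidence overlay matches unordered gene pairs and trait SNPs, and is idempotent", {
  pairs <- mk_pair()
  ann <- dplyr::bind_rows(mk_ann("s1", "GA", "PROMOTER"),
                          mk_ann("s2", "GB", "CDS", "SYNONYMOUS"))
  ldgis <- build_interactions(annotate_pairs(pairs, ann))

  ppi <- tibble::tibble(gene1 = "GB", gene2 = "GA")  # reversed order
  traits <- tibble::tibble(snp_id = "s2", trait = "height")
  ov <- overlay_evidence(ldgis, ppi = ppi, traits = traits)
  expect_equal(ov$known_evidence, "KNOWN_PPI,TRAIT_LINKED")

  # unmatched evidence genes are ignored but counted
  ppi2 <- tibble::tibble(gene1 = c("GB", "ZZ1"), gene2 = c("GA", "ZZ2"))
  ov2 <- overlay_evidence(ldgis, ppi = ppi2)
  expect_equal(attr(ov2, "ignored_evidence_genes"), 2L)

  # no evidence anywhere -> uncharacterized (empty flag set)
  expect_equal(overlay_evidence(ldgis)$known_evidence, "")

  # applying the overlay twice equals applying it once
  twice <- overlay_evidence(ov, ppi = ppi, traits = traits)
  expect_equal(as.data.frame(twice), as.data.frame(ov))

  coexp <- tibble::tibble(a = "GA", b = "GB")
  ovc <- overlay_evidence(ldgis, coexp = coexp)
  expect_equal(ovc$known_evidence, "KNOWN_COEXPRESSION")
})

test_that("pair and interaction queries compose with intersection semantics", {
  pairs <- dplyr::bind_rows(
    mk_pair("s1", "s2"),
    dplyr::mutate(mk_pair("s3", "s4"), pos1 = 5000L, r2 = 1,
                  population = "P2"))
  expect_equal(filter_pairs(pairs, snp_id = "s4")$snp1_id, "s3")
  expect_equal(nrow(filter_pairs(pairs, region = "chr1:0-1000")), 1L)
  expect_equal(nrow(filter_pairs(pairs, region = "chr1:0-1000",
                                 population = "P2")), 0L)
  expect_equal(nrow(filter_pairs(pairs, r2_min = 1.0)), 1L)
  expect_error(filter_pairs(pairs, region = "chr1:10"), "malformed")

  ann <- dplyr::bind_rows(
    mk_ann("s1", "GA", "PROMOTER"), mk_ann("s2", "GB", "UTR", side = 5L),
    mk_ann("s3", "GB", "CDS", "SYNONYMOUS"),
    mk_ann("s4", "GC", "CDS", "NONSYNONYMOUS"))
  ldgis <- build_interactions(annotate_pairs(pairs, ann))
  expect_equal(nrow(filter_interactions(ldgis, gene_id = "GB")), 2L)
  expect_equal(nrow(filter_interactions(ldgis, category = "CDS-CDS")), 1L)
  expect_equal(nrow(filter_interactions(ldgis, category = "CDS-CDS",
                                        population = "P1")), 0L)
  expect_error(filter_interactions(ldgis, category = "CDS-PROMOTER"))
})
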