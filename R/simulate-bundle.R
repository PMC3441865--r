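# Gene-landscape construction and the full simulation bundle.

SYN_CODON <- "CTG"     # 4-fold degenerate Leu codon; third-base G->A stays Leu
NONSYN_CODON <- "CAT"  # His; middle-base A->G gives Arg

# per-strand genomic ref/alt alleles realizing the designed CDS change
cds_snp_alleles <- function(feature, strand) {
  if (feature == "CDS_SYN") {
    if (strand == "+") c(ref = "G", alt = "A") else c(ref = "C", alt = "T")
  } else {
    if (strand == "+") c(ref = "A", alt = "G") else c(ref = "T", alt = "C")
  }
}

# builds genes/transcripts/exons/CDS for one slot gene; geometry is fixed
# relative to the gene-body start g (see sim_layout)
slot_gene_tables <- function(gene_id, chrom, strand, g) {
  list(
    gene = tibble(gene_id = gene_id, gene_name = gene_id, chrom = chrom,
                  strand = strand),
    transcript = tibble(transcript_id = paste0(gene_id, ".t1"),
                        gene_id = gene_id),
    exons = tibble(transcript_id = paste0(gene_id, ".t1"),
                   start = c(g, g + 400L), end = c(g + 200L, g + 800L)),
    cds = tibble(transcript_id = paste0(gene_id, ".t1"),
                 start = c(g + 101L, g + 400L), end = c(g + 200L, g + 550L))
  )
}

# designed 249-nt CDS in reading-frame order: random codons with the
# feature-bearing codon overwritten (codon 33 on +, codon 0 on -)
design_cds <- function(feature, strand) {
  s <- paste(sample(c("A", "C", "G", "T"), 249L, replace = TRUE),
             collapse = "")
  if (feature %in% c("CDS_SYN", "CDS_NONSYN")) {
    codon <- if (feature == "CDS_SYN") SYN_CODON else NONSYN_CODON
    idx <- if (strand == "+") 33L else 0L
    substr(s, idx * 3L + 1L, idx * 3L + 3L) <- codon
  }
  s
}

# writes a reading-frame CDS into the genome at the two CDS segments
write_cds_into_genome <- function(seq_chr, cds_seq, g, strand) {
  revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }
  if (strand == "+") {
    substr(seq_chr, g + 102L, g + 200L) <- substr(cds_seq, 1L, 99L)
    substr(seq_chr, g + 401L, g + 550L) <- substr(cds_seq, 100L, 249L)
  } else {
    substr(seq_chr, g + 401L, g + 550L) <- revcomp(substr(cds_seq, 1L, 150L))
    substr(seq_chr, g + 102L, g + 200L) <- revcomp(substr(cds_seq, 151L, 249L))
  }
  seq_chr
}

#' Simulate the gene landscape for a configuration
#'
#' Builds a random genome plus gene models placed so that every planted
#' cross-chromosome SNP falls in its prescribed feature: promoter, 5'/3'
#' UTR, or a CDS position whose designed codon realizes the prescribed
#' synonymous/nonsynonymous effect (a 4-fold degenerate third position
#' versus an amino-acid-changing middle position). Genes alternate
#' strands; minus-strand CDS sequence is written reverse-complemented so
#' reading-frame order is respected. One overlapping gene (when
#' configured) places the first planted SNP additionally in a second
#' gene's 3' UTR.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list with `models` ([gene_models]), `snps` (SNP table with
#'   ref/alt filled), `track` ([hotspot_track]), and `placements` (the
#'   prescribed feature of every placed SNP: `snp_id`, `gene_id`,
#'   `feature` in promoter/UTR/CDS terms, `utr_side`, `coding_effect`).
#' @export
simulate_gene_landscape <- function(config = sim_config(), seed = 1L) {
  with_preserved_seed(seed, simulate_gene_landscape_impl(config))
}

simulate_gene_landscape_impl <- function(config) {
  layout <- sim_layout(config)
  snps <- layout$snps
  snps$ref <- NA_character_
  snps$alt <- NA_character_
  chroms <- c("chr1", "chr2")
  genome_chr <- setNames(lapply(chroms, function(chr) {
    paste(sample(c("A", "C", "G", "T"), layout$chrom_length, replace = TRUE),
          collapse = "")
  }), chroms)

  nc <- config$n_cross_pairs
  genes <- list(); transcripts <- list(); exons <- list(); cds <- list()
  placements <- list()

  add_gene <- function(tabs) {
    genes[[length(genes) + 1L]] <<- tabs$gene
    transcripts[[length(transcripts) + 1L]] <<- tabs$transcript
    exons[[length(exons) + 1L]] <<- tabs$exons
    cds[[length(cds) + 1L]] <<- tabs$cds
  }

  for (side in 1:2) {
    chrom <- chroms[[side]]
    for (i in seq_len(nc)) {
      gene_id <- sprintf("G%s%02d", c("A", "B")[[side]], i)
      strand <- layout$gene_strand[[i]]
      g <- layout$gene_start[[i]]
      add_gene(slot_gene_tables(gene_id, chrom, strand, g))
      sel <- which(snps$role == "cross_chrom" & snps$pair %in% i &
                     snps$chrom == chrom)
      feature <- snps$feature[sel]
      cds_seq <- design_cds(feature, strand)
      genome_chr[[chrom]] <- write_cds_into_genome(genome_chr[[chrom]],
                                                   cds_seq, g, strand)
      feat_class <- c(PROMOTER = "PROMOTER", UTR5 = "UTR", UTR3 = "UTR",
                      CDS_SYN = "CDS", CDS_NONSYN = "CDS")[[feature]]
      side5 <- c(PROMOTER = NA_integer_, UTR5 = 5L, UTR3 = 3L,
                 CDS_SYN = NA_integer_, CDS_NONSYN = NA_integer_)[[feature]]
      eff <- c(PROMOTER = NA_character_, UTR5 = NA_character_,
               UTR3 = NA_character_, CDS_SYN = "SYNONYMOUS",
               CDS_NONSYN = "NONSYNONYMOUS")[[feature]]
      placements[[length(placements) + 1L]] <- tibble(
        snp_id = snps$snp_id[sel], gene_id = gene_id,
        feature = feat_class, utr_side = side5, coding_effect = eff
      )
      if (feature %in% c("CDS_SYN", "CDS_NONSYN")) {
        al <- cds_snp_alleles(feature, strand)
        snps$ref[sel] <- al[["ref"]]
        snps$alt[sel] <- al[["alt"]]
      }
    }
  }

  # overlapping gene: first planted SNP (designed CDS_NONSYN on a + strand
  # gene) also sits in the 3' UTR of a second, overlapping gene
  if (config$overlap_gene) {
    sel <- which(snps$role == "cross_chrom" & snps$pair %in% 1L &
                   snps$chrom == "chr1")
    p <- snps$pos[sel]
    g2 <- p - 700L
    ov <- list(
      gene = tibble(gene_id = "GOV1", gene_name = "GOV1", chrom = "chr1",
                    strand = "+"),
      transcript = tibble(transcript_id = "GOV1.t1", gene_id = "GOV1"),
      exons = tibble(transcript_id = "GOV1.t1", start = g2, end = g2 + 800L),
      cds = tibble(transcript_id = "GOV1.t1", start = g2 + 101L,
                   end = g2 + 203L)
    )
    add_gene(ov)
    placements[[length(placements) + 1L]] <- tibble(
      snp_id = snps$snp_id[sel], gene_id = "GOV1", feature = "UTR",
      utr_side = 3L, coding_effect = NA_character_
    )
  }

  # fill ref/alt for all SNPs without designed alleles from the genome
  need <- is.na(snps$ref)
  bases <- c("A", "C", "G", "T")
  for (k in which(need)) {
    b <- substr(genome_chr[[snps$chrom[[k]]]], snps$pos[[k]] + 1L,
                snps$pos[[k]] + 1L)
    snps$ref[[k]] <- b
    snps$alt[[k]] <- bases[[match(b, bases) %% 4L + 1L]]
  }

  genome <- Biostrings::DNAStringSet(unlist(genome_chr))
  if (length(genes) == 0L) {
    genes <- list(tibble(gene_id = character(), gene_name = character(),
                         chrom = character(), strand = character()))
    transcripts <- list(tibble(transcript_id = character(),
                               gene_id = character()))
    exons <- list(tibble(transcript_id = character(), start = integer(),
                         end = integer()))
    cds <- list(tibble(transcript_id = character(), start = integer(),
                       end = integer()))
  }
  models <- gene_models(dplyr::bind_rows(genes), dplyr::bind_rows(transcripts),
                        dplyr::bind_rows(exons), dplyr::bind_rows(cds),
                        genome = genome)
  list(models = models, snps = snps, track = layout$hotspots,
       placements = dplyr::bind_rows(placements))
}

#' Simulate a phased haplotype panel with planted LD structure
#'
#' Generates the panel described by the configuration: background SNP
#' columns drawn independently, planted pairs realized at their target
#' r-squared via [plant_pair()], and decoy pairs exercising both halves of
#' the long-range filter. Fully reproducible per seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list with `panel` ([haplotype_panel]), `track`
#'   ([hotspot_track]), and `truth` — a tibble of planted pairs with
#'   `snp1_id`, `snp2_id`, `class`, `target_r2`, `achieved_r2`,
#'   `long_range` (whether the pair satisfies the positional criterion).
#' @export
simulate_panel <- function(config = sim_config(), seed = 1L) {
  bundle <- with_preserved_seed(seed, simulate_all_impl(config))
  bundle[c("panel", "track", "truth")]
}

simulate_all_impl <- function(config) {
  land <- simulate_gene_landscape_impl(config)
  snps <- land$snps
  n_hap <- 2L * config$n_individuals
  cols <- matrix(NA_integer_, nrow = n_hap, ncol = nrow(snps))

  truth <- list()
  plant_role <- function(role, idx_pairs, targets, freqs, class) {
    for (j in seq_along(idx_pairs)) {
      i1 <- which(snps$role == role & snps$pair == idx_pairs[[j]] &
                    grepl("_1$", snps$snp_id))
      i2 <- which(snps$role == role & snps$pair == idx_pairs[[j]] &
                    grepl("_2$", snps$snp_id))
      pl <- plant_pair(n_hap, targets[[j]], freqs[[j]], freqs[[j]])
      cols[, i1] <<- pl$col1
      cols[, i2] <<- pl$col2
      truth[[length(truth) + 1L]] <<- tibble(
        snp1_id = snps$snp_id[[i1]], snp2_id = snps$snp_id[[i2]],
        class = class, target_r2 = targets[[j]],
        achieved_r2 = pl$achieved_r2,
        long_range = class != "SAME_BLOCK"
      )
    }
  }

  if (config$n_cross_pairs > 0L) {
    plant_role("cross_chrom", seq_len(config$n_cross_pairs),
               config$cross_targets, config$cross_freqs, "CROSS_CHROM")
  }
  if (config$n_same_block_decoys > 0L) {
    plant_role("same_block", seq_len(config$n_same_block_decoys),
               rep(1.0, config$n_same_block_decoys),
               rep(0.5, config$n_same_block_decoys), "SAME_BLOCK")
  }
  if (config$n_cross_hotspot_decoys > 0L) {
    plant_role("cross_hotspot", seq_len(config$n_cross_hotspot_decoys),
               rep(config$decoy_weak_r2, config$n_cross_hotspot_decoys),
               rep(0.5, config$n_cross_hotspot_decoys), "CROSS_HOTSPOT")
  }
  for (k in which(snps$role == "background")) {
    maf <- runif(1L, config$background_maf_range[[1L]],
                 config$background_maf_range[[2L]])
    cols[, k] <- rbinom(n_hap, 1L, maf)
  }

  sample_ids <- sprintf("S%03d", seq_len(config$n_individuals))
  panel <- haplotype_panel(cols,
                           snps[, c("snp_id", "chrom", "pos", "ref", "alt")],
                           sample_ids, population_label = config$population)
  list(panel = panel, track = land$track,
       truth = dplyr::bind_rows(truth),
       models = land$models, placements = land$placements,
       snps = snps)
}

# expected gene-interaction table implied by the prescriptions: the
# cross product of each planted pair's placements, categorized and
# aggregated exactly as build_interactions() defines
expected_ldgi_table <- function(truth, placements, population) {
  rows <- list()
  emitted <- truth[truth$class == "CROSS_CHROM", ]
  for (r in seq_len(nrow(emitted))) {
    a1 <- placements[placements$snp_id == emitted$snp1_id[[r]], ]
    a2 <- placements[placements$snp_id == emitted$snp2_id[[r]], ]
    for (u in seq_len(nrow(a1))) {
      for (v in seq_len(nrow(a2))) {
        if (a1$gene_id[[u]] == a2$gene_id[[v]]) next
        ct <- categorize_pair(a1$feature[[u]], a2$feature[[v]],
                              a1$coding_effect[[u]], a2$coding_effect[[v]])
        rows[[length(rows) + 1L]] <- tibble(
          gene1 = min(a1$gene_id[[u]], a2$gene_id[[v]]),
          gene2 = max(a1$gene_id[[u]], a2$gene_id[[v]]),
          category = ct$category, coding_subtype = ct$coding_subtype,
          population = population,
          pair_id = paste(emitted$snp1_id[[r]], emitted$snp2_id[[r]],
                          sep = "|")
        )
      }
    }
  }
  x <- dplyr::distinct(dplyr::bind_rows(rows))
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$gene1, .data$gene2, .data$category,
                    .data$coding_subtype, .data$population),
    support_count = dplyr::n_distinct(.data$pair_id),
    supporting_snp_pairs = paste(sort(unique(.data$pair_id)), collapse = ";"),
    .groups = "drop")
  dplyr::arrange(out, .data$gene1, .data$gene2, .data$category,
                 .data$coding_subtype, .data$population)
}

#' Simulate and write a complete fixture bundle
#'
#' Runs the full simulator and writes every input the pipeline reads:
#' haplotype table and phased VCF (with sample-population map), hotspot
#' BED3, gene-model GFF3, genome FASTA, and a JSON truth manifest holding
#' the planted pairs (with achieved r-squared), the prescribed SNP
#' placements, and the expected gene-interaction table.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seeds give identical files.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`panel`, `track`,
#'   `models`, `truth`, `placements`, `expected_ldgi`) and `paths` to the
#'   written files.
#' @export
simulate_bundle <- function(config = sim_config(), seed = 1L,
                            dir = tempfile("ldgi_sim_")) {
  bundle <- with_preserved_seed(seed, simulate_all_impl(config))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    haps = file.path(dir, paste0("haplotypes_", config$population, ".tsv")),
    vcf = file.path(dir, "panel.vcf"),
    popmap = file.path(dir, "popmap.tsv"),
    hotspots = file.path(dir, "hotspots.bed"),
    gff3 = file.path(dir, "genes.gff3"),
    fasta = file.path(dir, "genome.fa"),
    manifest = file.path(dir, "manifest.json")
  )
  write_haplotype_table(bundle$panel, paths$haps)
  write_phased_vcf(bundle$panel, paths$vcf)
  readr::write_tsv(tibble(sample_id = bundle$panel$sample_ids,
                          population = config$population),
                   paths$popmap, col_names = FALSE, progress = FALSE)
  write_hotspots_bed(bundle$track, paths$hotspots)
  write_gene_models_gff3(bundle$models, paths$gff3, paths$fasta)

  expected <- expected_ldgi_table(bundle$truth, bundle$placements,
                                  config$population)
  manifest <- list(
    seed = seed,
    population = config$population,
    n_individuals = config$n_individuals,
    planted_pairs = bundle$truth,
    placements = bundle$placements,
    expected_ldgi = expected
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(bundle, list(expected_ldgi = expected, paths = paths,
                           dir = dir)))
}
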