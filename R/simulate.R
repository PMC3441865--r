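# Seeded simulator: phased panels with planted LD pairs, hotspot tracks,
# gene models and genome sequence, all truth-annotated so every pipeline
# stage can be checked against a known answer.
#
# Planting inverts the r-squared formula analytically: given target r2 and
# the two allele frequencies, the positive-D root fixes the four haplotype
# frequencies exactly; integer rounding (largest remainder) then bounds the
# achieved-vs-target gap by 4/n.

#' Plant two haplotype columns at a target r-squared
#'
#' Solves the LD equations for the joint haplotype frequency `P_AB` given
#' the target r-squared and the two major-allele frequencies (taking the
#' positive-D root), rounds the four haplotype-class frequencies to
#' integer counts summing to `n_haplotypes` (largest-remainder method),
#' and emits the two allele columns in a seeded random row order. The
#' achieved r-squared is recomputed from the realized integer counts; its
#' distance from the target is bounded by `4 / n_haplotypes`.
#'
#' @param n_haplotypes Even number of haplotypes (40 or more for panel
#'   use; small n is allowed for worked examples).
#' @param target_r2 Target r-squared in `[0, 1]`.
#' @param p_a,p_b Frequencies of the reference-coded allele at the two
#'   loci, in `(0, 1)`.
#' @param seed Optional integer seed for the row shuffle; when `NULL` the
#'   current RNG state is used (as inside [simulate_panel()]).
#' @return A list with `col1`, `col2` (integer allele vectors), `counts`
#'   (named AB/Ab/aB/ab), and `achieved_r2`.
#' @export
plant_pair <- function(n_haplotypes, target_r2, p_a = 0.5, p_b = 0.5,
                       seed = NULL) {
  stopifnot(n_haplotypes %% 2L == 0L,
            target_r2 >= 0, target_r2 <= 1,
            p_a > 0, p_a < 1, p_b > 0, p_b < 1)
  prod4 <- p_a * (1 - p_a) * p_b * (1 - p_b)
  d_max <- min(p_a * (1 - p_b), (1 - p_a) * p_b)
  r2_max <- d_max^2 / prod4
  if (target_r2 > r2_max + 1e-9) {
    stop(sprintf(
      "INFEASIBLE: target r2 = %g unattainable at frequencies (%g, %g); maximum attainable r2 = %g",
      target_r2, p_a, p_b, r2_max), call. = FALSE)
  }
  d <- sqrt(target_r2 * prod4)  # positive-D root
  freqs <- c(AB = p_a * p_b + d,
             Ab = p_a * (1 - p_b) - d,
             aB = (1 - p_a) * p_b - d,
             ab = (1 - p_a) * (1 - p_b) + d)
  freqs <- pmax(freqs, 0)
  counts <- largest_remainder(freqs, n_haplotypes)
  if ((counts[["AB"]] + counts[["Ab"]]) %in% c(0L, n_haplotypes) ||
      (counts[["AB"]] + counts[["aB"]]) %in% c(0L, n_haplotypes)) {
    stop("planted counts leave a locus monomorphic; adjust frequencies or n",
         call. = FALSE)
  }
  col1 <- rep(c(0L, 0L, 1L, 1L), counts)
  col2 <- rep(c(0L, 1L, 0L, 1L), counts)
  shuffle <- function() sample.int(n_haplotypes)
  ord <- if (is.null(seed)) shuffle() else with_preserved_seed(seed, shuffle())
  list(col1 = col1[ord], col2 = col2[ord], counts = counts,
       achieved_r2 = r2_from_counts(counts))
}

largest_remainder <- function(freqs, n) {
  raw <- freqs * n
  base <- floor(raw)
  short <- as.integer(round(n - sum(base)))
  frac <- raw - base
  if (short > 0L) {
    give <- order(frac, decreasing = TRUE)[seq_len(short)]
    base[give] <- base[give] + 1L
  }
  setNames(as.integer(base), names(freqs))
}

r2_from_counts <- function(counts) {
  n <- sum(counts)
  p_a <- (counts[[1L]] + counts[[2L]]) / n
  p_b <- (counts[[1L]] + counts[[3L]]) / n
  d <- counts[[1L]] / n - p_a * p_b
  d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
}

with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Defines the study conditions of the default simulated panel: one
#' population of 50 individuals (100 haplotypes); two chromosomes; 25
#' planted cross-chromosome SNP pairs with target r-squared between 0.9
#' and 1.0 at matched allele frequencies 0.3-0.5 (so the achieved values
#' stay at or above 0.9 after integer rounding); 10 same-block decoy pairs
#' at complete LD (strong LD the positional filter must reject); 5
#' cross-hotspot decoy pairs at weak LD (long-range candidates the LD
#' threshold must reject); and 25 independent background SNPs per
#' chromosome with allele frequencies drawn from `background_maf_range`.
#' Each planted cross-chromosome SNP is embedded in its own gene with a
#' prescribed feature (promoter, 5'/3' UTR, or a CDS site designed to be
#' synonymous or nonsynonymous), genes alternating strands; one SNP
#' additionally falls in the UTR of an overlapping second gene so
#' duplicate-placement records are always exercised.
#'
#' @param n_individuals Individuals in the panel (haplotypes are twice
#'   this).
#' @param population Population label.
#' @param n_cross_pairs Planted cross-chromosome pairs.
#' @param cross_targets,cross_freqs Target r-squared and allele frequency
#'   per planted pair (recycled to `n_cross_pairs`).
#' @param n_same_block_decoys Same-block decoy pairs at target r2 = 1.
#' @param n_cross_hotspot_decoys Cross-hotspot decoy pairs at weak LD.
#' @param decoy_weak_r2 Target r-squared of the weak decoys.
#' @param n_background_per_chrom Independent background SNPs per
#'   chromosome.
#' @param background_maf_range Range of background minor-allele
#'   frequencies.
#' @param overlap_gene Add the overlapping-gene placement for the first
#'   planted SNP.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 50L,
                       population = "POP1",
                       n_cross_pairs = 25L,
                       cross_targets = rep(c(0.9, 0.925, 0.95, 0.975, 1.0), 5L),
                       cross_freqs = rep(c(0.5, 0.55, 0.6, 0.65, 0.7), each = 5L),
                       n_same_block_decoys = 10L,
                       n_cross_hotspot_decoys = 5L,
                       decoy_weak_r2 = 0.2,
                       n_background_per_chrom = 25L,
                       background_maf_range = c(0.1, 0.5),
                       overlap_gene = TRUE) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    population = population,
    n_cross_pairs = as.integer(n_cross_pairs),
    cross_targets = rep_len(cross_targets, n_cross_pairs),
    cross_freqs = rep_len(cross_freqs, n_cross_pairs),
    n_same_block_decoys = as.integer(n_same_block_decoys),
    n_cross_hotspot_decoys = as.integer(n_cross_hotspot_decoys),
    decoy_weak_r2 = decoy_weak_r2,
    n_background_per_chrom = as.integer(n_background_per_chrom),
    background_maf_range = background_maf_range,
    overlap_gene = isTRUE(overlap_gene) && n_cross_pairs >= 1L
  )
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic genomic layout derived from the config: gene slots, SNP
# positions, hotspot intervals. Slot width 6000 bp holds one gene, its 2 kb
# promoter and flanking space; hotspots sit between consecutive slots.
SLOT_W <- 6000L
SLOT_MARGIN <- 2000L

# feature of planted SNP i on each side; the first pairs pin down all six
# categories and all three CDS-CDS subtypes, the rest cycle
plant_features <- function(n) {
  f1_head <- c("CDS_NONSYN", "CDS_NONSYN", "CDS_SYN", "PROMOTER",
               "PROMOTER", "PROMOTER", "CDS_SYN", "UTR5")
  f2_head <- c("CDS_SYN", "CDS_NONSYN", "CDS_SYN", "PROMOTER",
               "CDS_NONSYN", "UTR5", "UTR3", "UTR3")
  cyc <- c("PROMOTER", "UTR5", "CDS_SYN", "UTR3", "CDS_NONSYN")
  if (n == 0L) return(list(f1 = character(0), f2 = character(0)))
  i <- seq_len(n)
  f1 <- ifelse(i <= 8L, f1_head[pmin(i, 8L)], cyc[(i - 9L) %% 5L + 1L])
  f2 <- ifelse(i <= 8L, f2_head[pmin(i, 8L)], cyc[(i - 7L) %% 5L + 1L])
  list(f1 = f1, f2 = f2)
}

# SNP offset within a slot for each prescribed feature; g is the gene-body
# start (slot_start + 2500), gene body is 800 bp: exons [g,g+200) and
# [g+400,g+800), CDS [g+101,g+200) + [g+400,g+550) (249 nt)
feature_offset <- function(feature, strand) {
  plus <- c(PROMOTER = -1000L, UTR5 = 50L, UTR3 = 600L,
            CDS_SYN = 402L, CDS_NONSYN = 401L)
  minus <- c(PROMOTER = 1800L, UTR5 = 600L, UTR3 = 50L,
             CDS_SYN = 547L, CDS_NONSYN = 548L)
  if (strand == "+") plus[[feature]] else minus[[feature]]
}

sim_layout <- function(config) {
  nc <- config$n_cross_pairs
  feats <- plant_features(nc)
  slot_start <- SLOT_MARGIN + (seq_len(nc) - 1L) * SLOT_W
  strand <- c("+", "-")[(seq_len(nc) - 1L) %% 2L + 1L]
  g <- slot_start + 2500L

  place_side <- function(chrom, side_feats, suffix) {
    tibble(
      snp_id = sprintf("snp_cc%02d_%s", seq_len(nc), suffix),
      chrom = chrom,
      pos = as.integer(g + vapply(seq_len(nc), function(i) {
        feature_offset(side_feats[[i]], strand[[i]])
      }, integer(1L))),
      role = "cross_chrom",
      pair = seq_len(nc),
      feature = side_feats,
      gene_slot = seq_len(nc),
      strand = strand
    )
  }
  snps <- dplyr::bind_rows(place_side("chr1", feats$f1, "1"),
                           place_side("chr2", feats$f2, "2"))

  slots_end <- SLOT_MARGIN + nc * SLOT_W
  hotspots <- dplyr::bind_rows(lapply(c("chr1", "chr2"), function(chr) {
    tibble(chrom = chr,
           start = slot_start + 5400L,
           end = slot_start + 5700L)
  }))

  nsb <- config$n_same_block_decoys
  sb_start <- slots_end + 3300L
  if (nsb > 0L) {
    a <- sb_start + (seq_len(nsb) - 1L) * 250L
    snps <- dplyr::bind_rows(snps, tibble(
      snp_id = c(sprintf("snp_sb%02d_1", seq_len(nsb)),
                 sprintf("snp_sb%02d_2", seq_len(nsb))),
      chrom = "chr1",
      pos = as.integer(c(a, a + 100L)),
      role = "same_block",
      pair = rep(seq_len(nsb), 2L),
      feature = NA_character_, gene_slot = NA_integer_,
      strand = NA_character_
    ))
  }
  sb_end <- sb_start + max(0L, nsb) * 250L

  nxh <- config$n_cross_hotspot_decoys
  xh_start <- slots_end + 3300L
  if (nxh > 0L) {
    a <- xh_start + (seq_len(nxh) - 1L) * 1000L
    snps <- dplyr::bind_rows(snps, tibble(
      snp_id = c(sprintf("snp_xh%02d_1", seq_len(nxh)),
                 sprintf("snp_xh%02d_2", seq_len(nxh))),
      chrom = "chr2",
      pos = as.integer(c(a, a + 600L)),
      role = "cross_hotspot",
      pair = rep(seq_len(nxh), 2L),
      feature = NA_character_, gene_slot = NA_integer_,
      strand = NA_character_
    ))
    hotspots <- dplyr::bind_rows(hotspots, tibble(
      chrom = "chr2", start = a + 200L, end = a + 400L))
  }
  xh_end <- xh_start + max(0L, nxh) * 1000L

  nbg <- config$n_background_per_chrom
  bg1_start <- sb_end + 3000L
  bg2_start <- xh_end + 3000L
  if (nbg > 0L) {
    # a hotspot between the decoy and background regions keeps block
    # structure explicit on chr1
    hotspots <- dplyr::bind_rows(hotspots, tibble(
      chrom = "chr1", start = sb_end + 1200L, end = sb_end + 1500L))
    snps <- dplyr::bind_rows(snps, tibble(
      snp_id = c(sprintf("snp_bg_chr1_%03d", seq_len(nbg)),
                 sprintf("snp_bg_chr2_%03d", seq_len(nbg))),
      chrom = rep(c("chr1", "chr2"), each = nbg),
      pos = as.integer(c(bg1_start + (seq_len(nbg) - 1L) * 400L,
                         bg2_start + (seq_len(nbg) - 1L) * 400L)),
      role = "background",
      pair = NA_integer_, feature = NA_character_,
      gene_slot = NA_integer_, strand = NA_character_
    ))
  }

  chrom_length <- as.integer(max(snps$pos, hotspots$end) + 5000L)
  if (any(duplicated(snps[, c("chrom", "pos")]))) {
    stop("simulated SNP positions collide", call. = FALSE)
  }
  list(snps = snps, hotspots = hotspot_track(hotspots),
       slot_start = slot_start, gene_start = g, gene_strand = strand,
       chrom_length = chrom_length)
}
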