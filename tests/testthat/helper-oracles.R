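# Independent oracles, kept deliberately naive and separate from the
# package implementation paths they check.

# Brute-force LD from an explicit 2x2 haplotype contingency table: count
# every haplotype class literally, then apply the textbook formulas.
ld_brute <- function(col1, col2) {
  keep <- !is.na(col1) & !is.na(col2)
  x <- col1[keep]
  y <- col2[keep]
  n <- length(x)
  f1 <- sum(x == 1L) / n
  f2 <- sum(y == 1L) / n
  major1 <- if (f1 > 0.5) 1L else 0L
  major2 <- if (f2 > 0.5) 1L else 0L
  tab <- matrix(0L, 2L, 2L)  # rows: locus1 major/minor; cols: locus2
  for (k in seq_len(n)) {
    r <- if (x[[k]] == major1) 1L else 2L
    c <- if (y[[k]] == major2) 1L else 2L
    tab[r, c] <- tab[r, c] + 1L
  }
  p_a <- (tab[1, 1] + tab[1, 2]) / n
  p_b <- (tab[1, 1] + tab[2, 1]) / n
  p_ab <- tab[1, 1] / n
  d <- p_ab - p_a * p_b
  r2 <- d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  d_prime <- if (d < 0) {
    d / min(p_a * p_b, (1 - p_a) * (1 - p_b))
  } else if (d > 0) {
    d / min(p_a * (1 - p_b), (1 - p_a) * p_b)
  } else 0
  list(d = d, d_prime = d_prime, r2 = r2, n_used = n,
       monomorphic = p_a %in% c(0, 1) || p_b %in% c(0, 1))
}

# allele columns realizing given AB/Ab/aB/ab haplotype counts, with the
# 0-coded allele as A/B
cols_from_counts <- function(ab, a_b, ab_minor, abab) {
  counts <- c(ab, a_b, ab_minor, abab)
  list(x = rep(c(0L, 0L, 1L, 1L), counts),
       y = rep(c(0L, 1L, 0L, 1L), counts))
}

# random polymorphic column pair for property tests
random_cols <- function(n, miss_rate = 0) {
  repeat {
    x <- sample(0:1, n, replace = TRUE)
    y <- sample(0:1, n, replace = TRUE)
    if (miss_rate > 0) {
      x[runif(n) < miss_rate] <- NA_integer_
      y[runif(n) < miss_rate] <- NA_integer_
    }
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) >= 2 &&
        length(unique(x[keep])) == 2 && length(unique(y[keep])) == 2) {
      return(list(x = x, y = y))
    }
  }
}

# literal double-loop scan oracle: every unordered SNP pair, the two
# positional criteria verbatim, compute_ld per pair
scan_brute <- function(panel, track, r2_min, min_haplotypes = 40L) {
  snps <- panel$snps
  m <- nrow(snps)
  rows <- list()
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j <= i) next
      s1 <- snps[i, ]
      s2 <- snps[j, ]
      if (s1$chrom == s2$chrom) {
        lo <- min(s1$pos, s2$pos)
        hi <- max(s1$pos, s2$pos)
        iv <- track[track$chrom == s1$chrom, ]
        k <- sum(iv$start > lo & iv$end <= hi)
        if (k < 1L) next
        separation <- paste0("HOTSPOTS:", k)
      } else {
        separation <- "DIFF_CHROM"
      }
      st <- compute_ld(panel$alleles[, i], panel$alleles[, j],
                       min_haplotypes = min_haplotypes)
      if (st$status != "OK") next
      pass <- if (r2_min >= 1) st$r2 >= 1 - 1e-9 else st$r2 >= r2_min
      if (!pass) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        population = panel$population_label,
        snp1_id = s1$snp_id, chrom1 = s1$chrom, pos1 = s1$pos,
        snp2_id = s2$snp_id, chrom2 = s2$chrom, pos2 = s2$pos,
        r2 = st$r2, d_prime = st$d_prime, d = st$d,
        n_haplotypes = st$n_used, separation = separation
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(out)
  dplyr::arrange(out, chrom1, pos1, chrom2, pos2, snp1_id, snp2_id)
}

# full-enumeration genetic-code oracle via seqinr (independent of the
# Biostrings route used by the implementation)
codon_aa <- function(codon) {
  seqinr::translate(strsplit(tolower(codon), "")[[1]])
}

# one-gene models object on a short custom chromosome, for coding-effect
# and annotation tests
toy_gene_models <- function(seq, exons, cds, strand = "+",
                            chrom = "chrT", gene_id = "G1") {
  genome <- Biostrings::DNAStringSet(setNames(seq, chrom))
  gene_models(
    genes = tibble::tibble(gene_id = gene_id, gene_name = gene_id,
                           chrom = chrom, strand = strand),
    transcripts = tibble::tibble(transcript_id = paste0(gene_id, ".t1"),
                                 gene_id = gene_id),
    exons = tibble::tibble(transcript_id = paste0(gene_id, ".t1"),
                           start = exons[, 1], end = exons[, 2]),
    cds = tibble::tibble(transcript_id = paste0(gene_id, ".t1"),
                         start = cds[, 1], end = cds[, 2]),
    genome = genome
  )
}

# one gene per codon, all 64 codons on a single chromosome (slot k holds
# codon k as CDS [20k+10, 20k+13)); minus-strand variant carries the
# reverse complement on the genome so the reading frame spells the codon
codon_battery <- function(codons, strand) {
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  slot <- function(k) 20L * (k - 1L) + 10L
  seq_chr <- strrep("A", 20L * length(codons) + 20L)
  for (k in seq_along(codons)) {
    piece <- if (strand == "+") codons[[k]] else rc(codons[[k]])
    substr(seq_chr, slot(k) + 1L, slot(k) + 3L) <- piece
  }
  genome <- Biostrings::DNAStringSet(setNames(seq_chr, "chrT"))
  ids <- sprintf("C%02d", seq_along(codons))
  models <- gene_models(
    genes = tibble::tibble(gene_id = ids, gene_name = ids, chrom = "chrT",
                           strand = strand),
    transcripts = tibble::tibble(transcript_id = paste0(ids, ".t1"),
                                 gene_id = ids),
    exons = tibble::tibble(transcript_id = paste0(ids, ".t1"),
                           start = slot(seq_along(codons)) - 2L,
                           end = slot(seq_along(codons)) + 6L),
    cds = tibble::tibble(transcript_id = paste0(ids, ".t1"),
                         start = slot(seq_along(codons)),
                         end = slot(seq_along(codons)) + 3L),
    genome = genome
  )
  list(models = models, cds_start = slot(seq_along(codons)),
       tx = paste0(ids, ".t1"), genome_seq = seq_chr)
}

# small simulation config for brute-force comparisons (<= 60 SNPs)
small_sim_config <- function() {
  sim_config(n_individuals = 25L, n_cross_pairs = 6L,
             cross_targets = c(0.9, 1.0, 0.95, 0.925, 0.975, 0.9),
             cross_freqs = c(0.5, 0.6, 0.7, 0.55, 0.65, 0.5),
             n_same_block_decoys = 3L, n_cross_hotspot_decoys = 2L,
             n_background_per_chrom = 10L)
}
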