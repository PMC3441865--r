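# Long-range LD scan: enumerate SNP pairs that are positionally long
# range (different chromosomes, or separated by at least one merged
# recombination hotspot), then keep those in strong LD.

#' Count merged hotspot intervals between two positions
#'
#' An interval `[s, e)` counts only when it lies entirely inside the open
#' gap between the two SNP positions (`pos_lo < s` and `e <= pos_hi`): a
#' hotspot straddling either SNP does not cleanly separate the loci.
#'
#' @param chrom Chromosome name.
#' @param pos_lo,pos_hi 0-based positions with `pos_lo < pos_hi`.
#' @param track A [hotspot_track].
#' @return Integer count of contained merged intervals.
#' @export
hotspots_between <- function(chrom, pos_lo, pos_hi, track) {
  stopifnot(pos_lo < pos_hi)
  iv <- track[track$chrom == chrom, ]
  sum(iv$start > pos_lo & iv$end <= pos_hi)
}

#' Test the long-range criterion for one SNP pair
#'
#' A pair is long range when the SNPs lie on different chromosomes, or on
#' the same chromosome with at least one recombination hotspot fully
#' between them. Same-chromosome pairs with no intervening hotspot are
#' presumed to share an LD block (where allele correlation can arise from
#' lack of recombination rather than interaction) and are rejected.
#'
#' @param snp1,snp2 Lists or one-row data frames with `chrom` and `pos`.
#' @param track A [hotspot_track].
#' @return A list with `long_range` (logical) and `separation`
#'   (`"DIFF_CHROM"`, `"HOTSPOTS:k"`, or `NA` when not long range).
#' @export
is_long_range <- function(snp1, snp2, track) {
  if (snp1$chrom != snp2$chrom) {
    return(list(long_range = TRUE, separation = "DIFF_CHROM"))
  }
  k <- hotspots_between(snp1$chrom, min(snp1$pos, snp2$pos),
                        max(snp1$pos, snp2$pos), track)
  if (k >= 1L) {
    list(long_range = TRUE, separation = paste0("HOTSPOTS:", k))
  } else {
    list(long_range = FALSE, separation = NA_character_)
  }
}

#' Drop panels below the population-size floor
#'
#' Subpopulations with fewer individuals give unstable haplotype-frequency
#' estimates; the default floor is 20 individuals.
#'
#' @param panels A list of [haplotype_panel] objects.
#' @param min_individuals Minimum individuals per retained panel.
#' @return The retained panels (named list); dropped panels are reported
#'   via `message()` and in the `dropped_populations` attribute.
#' @export
filter_population_size <- function(panels, min_individuals = 20L) {
  if (inherits(panels, "haplotype_panel")) panels <- list(panels)
  sizes <- vapply(panels, n_individuals, integer(1L))
  labs <- vapply(panels, function(p) p$population_label, character(1L))
  names(panels) <- labs
  keep <- sizes >= min_individuals
  if (any(!keep)) {
    message("dropping population(s) below ", min_individuals,
            " individuals: ",
            paste(sprintf("%s (%d)", labs[!keep], sizes[!keep]),
                  collapse = ", "))
  }
  if (!any(keep)) {
    stop("all populations fall below the ", min_individuals,
         "-individual floor", call. = FALSE)
  }
  out <- panels[keep]
  attr(out, "dropped_populations") <- labs[!keep]
  out
}

#' Scan one population panel for long-range LD SNP pairs
#'
#' Enumerates candidate SNP pairs with the positional filter first —
#' cross-chromosome pairs, plus same-chromosome pairs in different
#' hotspot-delimited blocks (verified by exact interval containment) — and
#' only then computes LD, emitting pairs with `r2 >= r2_min`. At the
#' complete-LD tier (`r2_min = 1`) membership uses a 1e-9 tolerance.
#'
#' @param panel A [haplotype_panel].
#' @param track A [hotspot_track].
#' @param r2_min Strong-LD threshold; one of 0.8, 0.9, 1.0.
#' @param min_haplotypes Minimum jointly non-missing haplotypes per pair
#'   (default 40, i.e. 20 individuals, mirroring the population floor).
#' @return A tibble with columns `population`, `snp1_id`, `chrom1`,
#'   `pos1`, `snp2_id`, `chrom2`, `pos2`, `r2`, `d_prime`, `d`,
#'   `n_haplotypes`, `separation`, sorted canonically. Skip counters
#'   (`monomorphic`, `low_n`) and the number of positional candidates are
#'   attached as the `counters` attribute.
#' @export
scan_population <- function(panel, track, r2_min = 0.8,
                            min_haplotypes = 40L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  r2_min <- check_r2_min(r2_min)
  snps <- panel$snps
  m <- nrow(snps)
  counters <- c(candidates = 0L, monomorphic = 0L, low_n = 0L)

  empty <- tibble(
    population = character(), snp1_id = character(), chrom1 = character(),
    pos1 = integer(), snp2_id = character(), chrom2 = character(),
    pos2 = integer(), r2 = double(), d_prime = double(), d = double(),
    n_haplotypes = integer(), separation = character()
  )
  if (m < 2L) {
    attr(empty, "counters") <- counters
    return(empty)
  }

  # hotspot-block id per SNP: number of merged intervals ending at or
  # before the SNP position (a different block id is necessary for k >= 1)
  block <- integer(m)
  for (chr in unique(snps$chrom)) {
    sel <- snps$chrom == chr
    ends <- sort(track$end[track$chrom == chr])
    block[sel] <- findInterval(snps$pos[sel], ends)
  }

  idx <- which(upper.tri(matrix(TRUE, m, m)), arr.ind = TRUE)
  i <- idx[, "row"]
  j <- idx[, "col"]
  diff_chrom <- snps$chrom[i] != snps$chrom[j]
  cand <- diff_chrom | (block[i] != block[j])
  i <- i[cand]; j <- j[cand]; diff_chrom <- diff_chrom[cand]

  # exact containment check for same-chromosome candidates
  sep <- character(length(i))
  keep <- logical(length(i))
  for (t in seq_along(i)) {
    if (diff_chrom[[t]]) {
      keep[[t]] <- TRUE
      sep[[t]] <- "DIFF_CHROM"
    } else {
      k <- hotspots_between(snps$chrom[[i[[t]]]],
                            min(snps$pos[[i[[t]]]], snps$pos[[j[[t]]]]),
                            max(snps$pos[[i[[t]]]], snps$pos[[j[[t]]]]),
                            track)
      keep[[t]] <- k >= 1L
      sep[[t]] <- paste0("HOTSPOTS:", k)
    }
  }
  i <- i[keep]; j <- j[keep]; sep <- sep[keep]
  counters[["candidates"]] <- length(i)

  # vectorized pairwise-complete haplotype counting over all candidates
  # (crossproducts of the alt-allele and non-missing indicator matrices);
  # the scalar compute_ld() is the reference route and must agree exactly
  a <- panel$alleles
  M <- !is.na(a)
  X <- a
  X[!M] <- 0L
  storage.mode(M) <- "double"
  storage.mode(X) <- "double"
  n_cc <- crossprod(M)            # jointly non-missing haplotypes
  c11 <- crossprod(X)             # alt at both loci
  c1x <- crossprod(X, M)          # alt at locus 1, observed at locus 2
  lin <- cbind(i, j)
  n_u <- n_cc[lin]
  n11 <- c11[lin]
  n1x <- c1x[lin]
  nx1 <- t(c1x)[lin]

  low_n <- n_u < max(2L, min_haplotypes)
  p1 <- ifelse(low_n, NA_real_, n1x / n_u)
  p2 <- ifelse(low_n, NA_real_, nx1 / n_u)
  mono <- !low_n & (p1 %in% c(0, 1) | p2 %in% c(0, 1))
  counters[["low_n"]] <- sum(low_n)
  counters[["monomorphic"]] <- sum(mono)

  # same integer-count arithmetic as compute_ld so both routes agree
  # exactly
  ok <- !low_n & !mono
  maj1 <- ok & p1 > 0.5           # tie -> reference allele is major
  maj2 <- ok & p2 > 0.5
  cmaj1 <- ifelse(maj1, n1x, n_u - n1x)
  cmaj2 <- ifelse(maj2, nx1, n_u - nx1)
  p_a <- cmaj1 / n_u
  p_b <- cmaj2 / n_u
  q_a <- (n_u - cmaj1) / n_u
  q_b <- (n_u - cmaj2) / n_u
  nAB <- ifelse(maj1,
                ifelse(maj2, n11, n1x - n11),
                ifelse(maj2, nx1 - n11, n_u - n1x - nx1 + n11))
  p_ab <- nAB / n_u
  d <- p_ab - p_a * p_b
  r2 <- (d * d) / ((p_a * q_a) * (p_b * q_b))
  d_prime <- ifelse(d < 0, d / pmin(p_a * p_b, q_a * q_b),
                    ifelse(d > 0, d / pmin(p_a * q_b, q_a * p_b), 0))

  hit <- which(ok & vapply(r2, function(v) isTRUE(r2_passes(v, r2_min)),
                           logical(1L)))
  out <- if (length(hit) == 0L) empty else tibble(
    population = panel$population_label,
    snp1_id = snps$snp_id[i[hit]], chrom1 = snps$chrom[i[hit]],
    pos1 = snps$pos[i[hit]],
    snp2_id = snps$snp_id[j[hit]], chrom2 = snps$chrom[j[hit]],
    pos2 = snps$pos[j[hit]],
    r2 = r2[hit], d_prime = d_prime[hit], d = d[hit],
    n_haplotypes = as.integer(n_u[hit]), separation = sep[hit]
  )
  out <- dplyr::arrange(out, .data$chrom1, .data$pos1, .data$chrom2,
                        .data$pos2, .data$snp1_id, .data$snp2_id)
  attr(out, "counters") <- counters
  out
}

#' Scan several population panels
#'
#' Applies [filter_population_size()] then [scan_population()] to each
#' retained panel and row-binds the results.
#'
#' @inheritParams scan_population
#' @param panels List of [haplotype_panel] objects.
#' @param min_individuals Population-size floor (individuals).
#' @return A tibble of long-range LD pairs across populations.
#' @export
scan_panels <- function(panels, track, r2_min = 0.8, min_individuals = 20L,
                        min_haplotypes = 40L) {
  kept <- filter_population_size(panels, min_individuals = min_individuals)
  dplyr::bind_rows(lapply(kept, scan_population, track = track,
                          r2_min = r2_min, min_haplotypes = min_haplotypes))
}

check_r2_min <- function(r2_min) {
  allowed <- c(0.8, 0.9, 1.0)
  if (length(r2_min) != 1L || !any(abs(r2_min - allowed) < 1e-12)) {
    stop("r2_min must be one of 0.8, 0.9, 1.0", call. = FALSE)
  }
  allowed[which.min(abs(r2_min - allowed))]
}
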