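# Linkage-disequilibrium statistics on phased haplotype columns.
#
# All frequencies are haplotype frequencies: each diploid individual
# contributes two rows (haplotypes) to a panel, and a "column" here is the
# allele vector of one SNP across all haplotypes, coded 0 (reference),
# 1 (alternate), or NA (missing).

#' Allele frequencies of one haplotype column
#'
#' Computes major/minor allele frequencies for a single SNP from its phased
#' haplotype column. Missing alleles (`NA`) are excluded from the counts.
#' Ties at frequency 0.5 designate the reference-coded allele (0) as major,
#' which fixes the sign of D deterministically; r-squared is invariant to
#' the choice.
#'
#' @param column Integer vector of alleles in `{0, 1, NA}`.
#' @return A list with `p_major`, `p_minor`, `major_allele` (0 or 1),
#'   `n_used` (non-missing haplotypes), and `monomorphic` (TRUE when only
#'   one allele is present among non-missing entries).
#' @examples
#' allele_frequencies(c(0L, 0L, 0L, 1L))
#' @export
allele_frequencies <- function(column) {
  keep <- !is.na(column)
  n_used <- sum(keep)
  if (n_used == 0L) {
    stop("allele_frequencies(): column is entirely missing", call. = FALSE)
  }
  x <- column[keep]
  k1 <- sum(x == 1L)
  major <- if (2L * k1 > n_used) 1L else 0L  # tie -> reference allele
  k_major <- if (major == 1L) k1 else n_used - k1
  # integer counts divided once: frequencies are exactly invariant under
  # allele relabeling and locus swap
  list(
    p_major = k_major / n_used,
    p_minor = (n_used - k_major) / n_used,
    major_allele = major,
    n_used = n_used,
    monomorphic = (k1 == 0L || k1 == n_used)
  )
}

#' Joint major-allele haplotype frequency for two SNPs
#'
#' Frequency of haplotypes carrying the major allele at both loci, after
#' pairwise-complete deletion (haplotypes missing at either locus are
#' dropped). Major alleles are determined on the pairwise-complete subset.
#'
#' @param col1,col2 Equal-length allele vectors in `{0, 1, NA}`.
#' @return A list with `p_ab` and `n_used`.
#' @export
haplotype_freq_ab <- function(col1, col2) {
  stopifnot(length(col1) == length(col2))
  keep <- !is.na(col1) & !is.na(col2)
  n_used <- sum(keep)
  if (n_used < 2L) {
    stop("haplotype_freq_ab(): fewer than 2 jointly non-missing haplotypes",
         call. = FALSE)
  }
  x <- col1[keep]
  y <- col2[keep]
  fx <- allele_frequencies(x)
  fy <- allele_frequencies(y)
  p_ab <- mean(x == fx$major_allele & y == fy$major_allele)
  list(p_ab = p_ab, n_used = n_used)
}

#' Linkage disequilibrium between two phased haplotype columns
#'
#' Computes the classical haplotype-frequency LD statistics for one SNP
#' pair: with `P_A`, `P_B` the major-allele frequencies at the two loci and
#' `P_AB` the frequency of haplotypes carrying both major alleles,
#' \deqn{D = P_{AB} - P_A P_B,\qquad
#'       r^2 = \frac{D^2}{P_A(1-P_A)\,P_B(1-P_B)},}
#' and `D'` is `D` normalized by its maximum attainable magnitude at the
#' given allele frequencies: `D / min(P_A P_B, P_a P_b)` when `D < 0`,
#' `D / min(P_A P_b, P_a P_B)` when `D > 0`, and defined as 0 when `D = 0`.
#'
#' Haplotypes missing at either locus are dropped (pairwise-complete
#' deletion) before any frequency is computed. If either locus is
#' monomorphic on that subset the statistics are undefined and the returned
#' object carries `status = "MONOMORPHIC"`; if fewer than `min_haplotypes`
#' haplotypes remain, `status = "LOW_N"`.
#'
#' @param col1,col2 Equal-length allele vectors in `{0, 1, NA}`.
#' @param min_haplotypes Minimum jointly non-missing haplotypes required
#'   (default 2; the scan applies its own, stricter floor).
#' @return An object of class `ld_stats`: a list with `p_a`, `p_b`
#'   (major-allele frequencies), `p_ab`, `d`, `d_prime`, `r2`, `n_used`,
#'   and `status` (`"OK"`, `"MONOMORPHIC"`, or `"LOW_N"`). Use [tidy()] for
#'   a one-row tibble.
#' @examples
#' # counts AB/Ab/aB/ab = 4/1/1/4 over 10 haplotypes
#' x <- c(rep(0L, 5), rep(1L, 5))
#' y <- c(rep(0L, 4), 1L, 0L, rep(1L, 4))
#' compute_ld(x, y)
#' @export
compute_ld <- function(col1, col2, min_haplotypes = 2L) {
  stopifnot(length(col1) == length(col2))
  keep <- !is.na(col1) & !is.na(col2)
  n_used <- sum(keep)
  out <- list(p_a = NA_real_, p_b = NA_real_, p_ab = NA_real_,
              d = NA_real_, d_prime = NA_real_, r2 = NA_real_,
              n_used = n_used, status = "OK")
  class(out) <- "ld_stats"
  if (n_used < max(2L, min_haplotypes)) {
    out$status <- "LOW_N"
    return(out)
  }
  x <- col1[keep]
  y <- col2[keep]
  fx <- allele_frequencies(x)
  fy <- allele_frequencies(y)
  if (fx$monomorphic || fy$monomorphic) {
    out$status <- "MONOMORPHIC"
    out$n_used <- n_used
    return(out)
  }
  p_a <- fx$p_major
  p_b <- fy$p_major
  q_a <- fx$p_minor
  q_b <- fy$p_minor
  p_ab <- sum(x == fx$major_allele & y == fy$major_allele) / n_used
  d <- p_ab - p_a * p_b
  # grouped per locus so the expression is symmetric under locus swap
  r2 <- (d * d) / ((p_a * q_a) * (p_b * q_b))
  d_prime <- if (d < 0) {
    d / min(p_a * p_b, q_a * q_b)
  } else if (d > 0) {
    d / min(p_a * q_b, q_a * p_b)
  } else {
    0
  }
  out$p_a <- p_a
  out$p_b <- p_b
  out$p_ab <- p_ab
  out$d <- d
  out$d_prime <- d_prime
  out$r2 <- r2
  out
}

#' @export
print.ld_stats <- function(x, ...) {
  if (x$status != "OK") {
    cat("<ld_stats> status:", x$status, " n_used:", x$n_used, "\n")
  } else {
    cat(sprintf(
      "<ld_stats> r2 = %.4f  D' = %.4f  D = %.4f  (P_A = %.3f, P_B = %.3f, n = %d)\n",
      x$r2, x$d_prime, x$d, x$p_a, x$p_b, x$n_used))
  }
  invisible(x)
}

#' @rdname compute_ld
#' @param x An `ld_stats` object.
#' @param ... Unused.
#' @method tidy ld_stats
#' @export
tidy.ld_stats <- function(x, ...) {
  tibble(
    p_a = x$p_a, p_b = x$p_b, p_ab = x$p_ab,
    d = x$d, d_prime = x$d_prime, r2 = x$r2,
    n_used = x$n_used, status = x$status
  )
}

#' @rdname compute_ld
#' @method glance ld_stats
#' @export
glance.ld_stats <- function(x, ...) {
  tibble(r2 = x$r2, d_prime = x$d_prime, n_used = x$n_used, status = x$status)
}

# Tolerance for the "complete LD" tier: r2 >= 1 - COMPLETE_LD_TOL counts
# as r2 = 1. Floating-point equality is not meaningful here.
COMPLETE_LD_TOL <- 1e-9

# Effective threshold test: at tier 1.0 use the complete-LD tolerance.
r2_passes <- function(r2, r2_min) {
  if (r2_min >= 1) r2 >= 1 - COMPLETE_LD_TOL else r2 >= r2_min
}
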