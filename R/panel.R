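# The haplotype panel container: a phased biallelic allele matrix for one
# population, with 2 rows per individual (haplotypes) and one column per SNP.

#' Construct a haplotype panel
#'
#' A panel holds the phased allele matrix of one population: `2 * n`
#' haplotype rows for `n` individuals, one column per SNP, entries 0
#' (reference allele), 1 (alternate allele) or `NA` (missing). Columns are
#' kept sorted by (chrom, pos); all positions are 0-based.
#'
#' @param alleles Integer matrix, `2 * length(sample_ids)` rows.
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos` (0-based),
#'   `ref`, `alt`.
#' @param sample_ids Character vector of individual identifiers.
#' @param population_label Population name for this panel.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, snps, sample_ids,
                            population_label = "POP") {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  snps <- as_tibble(snps)
  stopifnot(
    nrow(alleles) == 2L * length(sample_ids),
    ncol(alleles) == nrow(snps),
    all(c("snp_id", "chrom", "pos", "ref", "alt") %in% names(snps))
  )
  if (anyDuplicated(snps$snp_id)) {
    stop("duplicate snp_id in panel: ",
         paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !(alleles %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("panel alleles must be 0, 1 or NA", call. = FALSE)
  ord <- order(snps$chrom, snps$pos)
  snps <- snps[ord, ]
  alleles <- alleles[, ord, drop = FALSE]
  colnames(alleles) <- snps$snp_id
  rownames(alleles) <- paste(rep(sample_ids, each = 2L), c(0L, 1L), sep = ".")
  structure(
    list(population_label = population_label,
         sample_ids = sample_ids,
         alleles = alleles,
         snps = snps),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "<haplotype_panel> population %s: %d individuals (%d haplotypes) x %d SNPs on %d chromosome(s)\n",
    x$population_label, length(x$sample_ids), nrow(x$alleles),
    ncol(x$alleles), length(unique(x$snps$chrom))))
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$alleles)

#' Number of individuals in a panel
#' @param panel A `haplotype_panel`.
#' @return Integer count of individuals (half the haplotype rows).
#' @export
n_individuals <- function(panel) length(panel$sample_ids)

#' @rdname haplotype_panel
#' @param x A `haplotype_panel`.
#' @param ... Unused.
#' @return `tidy()` returns the SNP table with per-SNP alternate-allele
#'   frequency and missingness added.
#' @method tidy haplotype_panel
#' @export
tidy.haplotype_panel <- function(x, ...) {
  alt_freq <- colMeans(x$alleles == 1L, na.rm = TRUE)
  miss <- colMeans(is.na(x$alleles))
  dplyr::mutate(x$snps, alt_freq = unname(alt_freq),
                missing_rate = unname(miss),
                population = x$population_label)
}

#' @rdname haplotype_panel
#' @method glance haplotype_panel
#' @export
glance.haplotype_panel <- function(x, ...) {
  tibble(
    population = x$population_label,
    n_individuals = length(x$sample_ids),
    n_haplotypes = nrow(x$alleles),
    n_snps = ncol(x$alleles),
    n_chromosomes = length(unique(x$snps$chrom))
  )
}
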