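# Haplotype ingest: phased VCF and the plain haplotype-table dialect.
#
# Internal coordinates are 0-based half-open everywhere; the 1-based VCF
# and table-header positions are converted on read and restored on write.

#' Read phased haplotypes from a VCF
#'
#' Reads a VCF 4.x file with phased genotypes and splits the samples into
#' one [haplotype_panel] per population. Only biallelic SNVs whose
#' genotypes are all phased (`|` separator) are retained; multiallelic
#' records, indels and records with any unphased genotype are dropped and
#' counted. A phased missing genotype (`.|.`) is kept as missing alleles.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param population_map Either a data frame with columns `sample_id` and
#'   `population`, or the path of a two-column TSV (no header required if
#'   the first row parses as data; a `sample_id<TAB>population` header is
#'   accepted).
#' @return A named list of [haplotype_panel] objects, one per population
#'   present in the map, with attribute `dropped` giving per-reason record
#'   drop counts.
#' @export
read_phased_vcf <- function(path, population_map) {
  popmap <- load_population_map(population_map)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE, convertNA = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no records in VCF: ", path, call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT", convertNA = FALSE)
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = 1L)

  bases <- c("A", "C", "G", "T")
  snv <- fix$REF %in% bases & fix$ALT %in% bases & fix$REF != fix$ALT
  phased <- apply(gt, 1L, function(g) all(!is.na(g) & grepl("|", g, fixed = TRUE)))
  keep <- snv & phased
  dropped <- c(
    non_biallelic_snv = sum(!snv),
    unphased = sum(snv & !phased)
  )
  if (!any(keep)) stop("no phased biallelic SNV records retained from ", path,
                       call. = FALSE)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  vcf_samples <- colnames(gt)
  unknown <- setdiff(vcf_samples, popmap$sample_id)
  if (length(unknown) > 0L) {
    warning("samples absent from population map excluded: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  samples <- intersect(vcf_samples, popmap$sample_id)
  if (length(samples) == 0L) stop("no VCF sample appears in the population map",
                                  call. = FALSE)

  snp_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                   paste0(fix$CHROM, "_", fix$POS), fix$ID)
  snps <- tibble(
    snp_id = snp_id,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,  # 1-based VCF -> 0-based internal
    ref = fix$REF,
    alt = fix$ALT
  )

  # split "a|b" into two haplotype rows per sample; "." becomes NA
  hap_rows <- function(g) {
    parts <- strsplit(g, "|", fixed = TRUE)
    h1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    h2 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    rbind(h1, h2)
  }

  pops <- popmap[popmap$sample_id %in% samples, ]
  panels <- lapply(split(pops$sample_id, pops$population), function(ids) {
    mat <- matrix(NA_integer_, nrow = 2L * length(ids), ncol = nrow(snps))
    for (i in seq_along(ids)) {
      mat[c(2L * i - 1L, 2L * i), ] <- hap_rows(gt[, ids[[i]]])
    }
    if (any(!(mat %in% c(0L, 1L, NA_integer_)))) {
      stop("VCF genotypes contain allele codes other than 0/1", call. = FALSE)
    }
    mat
  })
  out <- lapply(names(panels), function(pop) {
    ids <- pops$sample_id[pops$population == pop]
    haplotype_panel(panels[[pop]], snps, ids, population_label = pop)
  })
  names(out) <- names(panels)
  attr(out, "dropped") <- dropped
  out
}

load_population_map <- function(population_map) {
  if (is.character(population_map) && length(population_map) == 1L) {
    popmap <- readr::read_tsv(population_map, col_names = FALSE,
                              col_types = "cc", progress = FALSE)
    names(popmap) <- c("sample_id", "population")
    popmap <- popmap[popmap$sample_id != "sample_id", ]  # tolerate a header row
  } else {
    popmap <- as_tibble(population_map)
    stopifnot(all(c("sample_id", "population") %in% names(popmap)))
  }
  popmap
}

#' Write a panel as a minimal phased VCF
#'
#' @param panel A [haplotype_panel].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  snps <- panel$snps
  a <- panel$alleles
  n <- length(panel$sample_ids)
  gt_chr <- matrix(as.character(a), nrow = nrow(a))
  gt_chr[is.na(gt_chr)] <- "."
  gt <- vapply(seq_len(n), function(i) {
    paste(gt_chr[2L * i - 1L, ], gt_chr[2L * i, ], sep = "|")
  }, character(nrow(snps)))
  if (nrow(snps) == 1L) gt <- matrix(gt, nrow = 1L)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(snps)), function(j) {
    paste(c(snps$chrom[[j]], snps$pos[[j]] + 1L, snps$snp_id[[j]],
            snps$ref[[j]], snps$alt[[j]], ".", "PASS", ".", "GT",
            gt[j, ]), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read the plain haplotype-table dialect
#'
#' The table dialect stores one haplotype per row. The header names each
#' SNP column as `snp_id:chrom:pos:ref:alt` with a 1-based position; the
#' first column holds `sampleID.hapIndex` with hapIndex 0 or 1. Cells are
#' `0`, `1`, or `.` for missing.
#'
#' @param path Path to the TSV.
#' @param population_label Population label for the returned panel.
#' @return A [haplotype_panel].
#' @export
read_haplotype_table <- function(path, population_label = "POP") {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(tab) < 2L) stop("haplotype table has no SNP columns: ", path,
                           call. = FALSE)
  snp_cols <- names(tab)[-1L]
  meta <- strsplit(snp_cols, ":", fixed = TRUE)
  if (any(lengths(meta) != 5L)) {
    stop("malformed SNP column header(s): ",
         paste(snp_cols[lengths(meta) != 5L], collapse = ", "), call. = FALSE)
  }
  snps <- tibble(
    snp_id = vapply(meta, `[`, "", 1L),
    chrom = vapply(meta, `[`, "", 2L),
    pos = as.integer(vapply(meta, `[`, "", 3L)) - 1L,  # header is 1-based
    ref = vapply(meta, `[`, "", 4L),
    alt = vapply(meta, `[`, "", 5L)
  )
  if (anyDuplicated(snps$snp_id)) {
    stop("duplicate snp_id in haplotype table: ",
         paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "),
         call. = FALSE)
  }
  hap_label <- tab[[1L]]
  sample_id <- sub("\\.[01]$", "", hap_label)
  hap_index <- sub("^.*\\.", "", hap_label)
  if (any(!hap_index %in% c("0", "1"))) {
    stop("haplotype row labels must end in .0 or .1", call. = FALSE)
  }
  counts <- table(sample_id)
  if (any(counts != 2L)) {
    stop("each sample needs exactly two haplotype rows; offending: ",
         paste(names(counts)[counts != 2L], collapse = ", "), call. = FALSE)
  }
  samples <- unique(sample_id)
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  if (any(!cells %in% c("0", "1", "."))) {
    stop("haplotype table cells must be 0, 1 or .", call. = FALSE)
  }
  mat <- matrix(NA_integer_, nrow = nrow(cells), ncol = ncol(cells))
  mat[cells == "0"] <- 0L
  mat[cells == "1"] <- 1L
  # order rows sample-by-sample, haplotype 0 then 1
  ord <- order(match(sample_id, samples), hap_index)
  haplotype_panel(mat[ord, , drop = FALSE], snps, samples,
                  population_label = population_label)
}

#' Write a panel in the haplotype-table dialect
#'
#' Inverse of [read_haplotype_table()]; a write/read round trip reproduces
#' the allele matrix exactly.
#'
#' @param panel A [haplotype_panel].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(panel, path) {
  snps <- panel$snps
  header <- paste(snps$snp_id, snps$chrom, snps$pos + 1L, snps$ref, snps$alt,
                  sep = ":")
  cells <- matrix(as.character(panel$alleles), nrow = nrow(panel$alleles))
  cells[is.na(cells)] <- "."
  out <- as.data.frame(cells, stringsAsFactors = FALSE)
  names(out) <- header
  out <- cbind(haplotype = rownames(panel$alleles), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
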