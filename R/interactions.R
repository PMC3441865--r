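# From annotated long-range LD SNP pairs to categorized gene-gene
# interactions, with optional overlays of external evidence.

FEATURE_ORDER <- c("PROMOTER", "CDS", "UTR")
CATEGORIES <- c("PROMOTER-PROMOTER", "PROMOTER-CDS", "PROMOTER-UTR",
                "CDS-CDS", "CDS-UTR", "UTR-UTR")

#' Category and coding subtype of one annotation pair
#'
#' The interaction category is the unordered combination of the two
#' features, rendered in the canonical element order
#' PROMOTER < CDS < UTR (six possible categories). CDS sides carry their
#' synonymous/nonsynonymous call into the coding subtype: CDS-CDS pairs
#' yield `NONSYN-NONSYN`, `NONSYN-SYN` or `SYN-SYN`; mixed pairs with one
#' CDS side yield `NONSYN-NA` or `SYN-NA`; pairs without a CDS side have
#' no subtype. A CDS side whose effect could not be called (non-codable
#' transcript) also yields `NA`.
#'
#' @param feature1,feature2 `"PROMOTER"`, `"CDS"` or `"UTR"`.
#' @param effect1,effect2 `"SYNONYMOUS"`, `"NONSYNONYMOUS"` or `NA` for
#'   non-CDS sides.
#' @return A list with `category` and `coding_subtype`.
#' @export
categorize_pair <- function(feature1, feature2,
                            effect1 = NA_character_,
                            effect2 = NA_character_) {
  stopifnot(feature1 %in% FEATURE_ORDER, feature2 %in% FEATURE_ORDER)
  f <- c(feature1, feature2)[order(match(c(feature1, feature2),
                                         FEATURE_ORDER))]
  category <- paste(f, collapse = "-")
  short <- function(e) {
    if (is.na(e)) NA_character_
    else if (e == "NONSYNONYMOUS") "NONSYN"
    else if (e == "SYNONYMOUS") "SYN"
    else NA_character_
  }
  effs <- c(short(effect1), short(effect2))
  is_cds <- c(feature1, feature2) == "CDS"
  subtype <- if (!any(is_cds)) {
    NA_character_
  } else if (all(is_cds)) {
    if (anyNA(effs)) NA_character_
    else paste(effs[order(match(effs, c("NONSYN", "SYN")))], collapse = "-")
  } else {
    e <- effs[is_cds]
    if (is.na(e)) NA_character_ else paste0(e, "-NA")
  }
  list(category = category, coding_subtype = subtype)
}

#' Expand LD pairs by their SNP annotations
#'
#' Joins each SNP of each pair against its feature annotations, producing
#' one row per (pair x annotation combination): a SNP placed in several
#' genes or features appears more than once, each placement a separate
#' row. Sides without any annotation are kept with `NA` gene/feature so
#' the pair-level record is preserved.
#'
#' @param pairs Pair tibble from [scan_population()]/[scan_panels()].
#' @param annotations Annotation tibble from [annotate_snps()].
#' @return The expanded tibble with `gene1/feature1/coding_effect1`,
#'   `gene2/feature2/coding_effect2`, `category`, `coding_subtype` added.
#' @export
annotate_pairs <- function(pairs, annotations) {
  ann <- dplyr::select(annotations, "snp_id", "gene_id", "gene_name",
                       "feature", "coding_effect")
  ann <- dplyr::distinct(ann)  # transcript multiplicity collapses at gene level
  out <- dplyr::left_join(pairs,
                          dplyr::rename(ann, snp1_id = "snp_id",
                                        gene1 = "gene_id",
                                        gene_name1 = "gene_name",
                                        feature1 = "feature",
                                        coding_effect1 = "coding_effect"),
                          by = "snp1_id", relationship = "many-to-many")
  out <- dplyr::left_join(out,
                          dplyr::rename(ann, snp2_id = "snp_id",
                                        gene2 = "gene_id",
                                        gene_name2 = "gene_name",
                                        feature2 = "feature",
                                        coding_effect2 = "coding_effect"),
                          by = "snp2_id", relationship = "many-to-many")
  cats <- purrr::pmap(
    list(out$feature1, out$feature2, out$coding_effect1, out$coding_effect2),
    function(f1, f2, e1, e2) {
      if (is.na(f1) || is.na(f2)) {
        list(category = NA_character_, coding_subtype = NA_character_)
      } else {
        categorize_pair(f1, f2, e1, e2)
      }
    })
  out$category <- vapply(cats, `[[`, "", "category")
  out$coding_subtype <- vapply(cats, function(x) x$coding_subtype,
                               character(1L))
  dplyr::arrange(out, .data$chrom1, .data$pos1, .data$chrom2, .data$pos2,
                 .data$snp1_id, .data$snp2_id, .data$gene1, .data$gene2,
                 .data$category)
}

#' Aggregate annotated pairs into gene-gene interactions
#'
#' Every (annotation of SNP 1) x (annotation of SNP 2) combination with
#' two distinct genes contributes one interaction record; records are
#' aggregated by (gene pair, category, coding subtype, population) with
#' support counts and the list of supporting SNP pairs. Combinations where
#' both SNPs fall in the same gene are dropped (a gene linked to itself is
#' not an interaction) and counted in the `self_pairs` attribute; the
#' pair-level rows retain that information.
#'
#' @param annotated_pairs Output of [annotate_pairs()].
#' @return A tibble with columns `gene1`, `gene2` (canonical order),
#'   `category`, `coding_subtype`, `population`, `support_count`,
#'   `supporting_snp_pairs` (semicolon-separated `snp1|snp2` ids),
#'   `known_evidence` (empty until [overlay_evidence()]).
#' @export
build_interactions <- function(annotated_pairs) {
  x <- annotated_pairs
  x <- x[!is.na(x$gene1) & !is.na(x$gene2), , drop = FALSE]
  self_pairs <- sum(x$gene1 == x$gene2)
  x <- x[x$gene1 != x$gene2, , drop = FALSE]
  x$pair_id <- paste(x$snp1_id, x$snp2_id, sep = "|")
  # canonical gene order; category is unordered so it is unaffected
  flip <- x$gene1 > x$gene2
  g1 <- ifelse(flip, x$gene2, x$gene1)
  g2 <- ifelse(flip, x$gene1, x$gene2)
  x$gene1 <- g1
  x$gene2 <- g2
  x <- dplyr::distinct(x, .data$gene1, .data$gene2, .data$category,
                       .data$coding_subtype, .data$population, .data$pair_id)
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$gene1, .data$gene2, .data$category,
                    .data$coding_subtype, .data$population),
    support_count = dplyr::n_distinct(.data$pair_id),
    supporting_snp_pairs = paste(sort(unique(.data$pair_id)),
                                 collapse = ";"),
    .groups = "drop"
  )
  out$known_evidence <- ""
  out <- dplyr::arrange(out, .data$gene1, .data$gene2, .data$category,
                        .data$coding_subtype, .data$population)
  attr(out, "self_pairs") <- self_pairs
  out
}

#' Overlay external evidence onto gene interactions
#'
#' Flags each interaction whose unordered gene pair appears in a known
#' protein-protein interaction list (`KNOWN_PPI`) or co-expression list
#' (`KNOWN_COEXPRESSION`), and interactions where either supporting SNP
#' has a trait entry (`TRAIT_LINKED`). Interactions with no flag are
#' potentially uncharacterized gene interactions. Flags are recomputed
#' from scratch, so applying the overlay twice equals applying it once.
#'
#' @param ldgis Interaction tibble from [build_interactions()].
#' @param ppi,coexp Two-column gene-pair data frames or TSV paths
#'   (unordered match; extra columns ignored).
#' @param traits Data frame or TSV path with columns `snp_id`, `trait`.
#' @return `ldgis` with `known_evidence` filled (comma-separated flags;
#'   empty string when uncharacterized). Evidence gene ids that match no
#'   interaction are counted in the `ignored_evidence_genes` attribute.
#' @export
overlay_evidence <- function(ldgis, ppi = NULL, coexp = NULL, traits = NULL) {
  read2 <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L) {
      x <- readr::read_tsv(x, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    }
    as_tibble(x)
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  ldgi_key <- key(ldgis$gene1, ldgis$gene2)
  known_genes <- unique(c(ldgis$gene1, ldgis$gene2))
  ignored <- 0L

  flags <- replicate(nrow(ldgis), character(0), simplify = FALSE)
  add_flag <- function(flags, hit, flag) {
    lapply(seq_along(flags), function(i) {
      if (hit[[i]]) union(flags[[i]], flag) else flags[[i]]
    })
  }

  for (spec in list(list(tab = read2(ppi), flag = "KNOWN_PPI"),
                    list(tab = read2(coexp), flag = "KNOWN_COEXPRESSION"))) {
    if (is.null(spec$tab) || nrow(spec$tab) == 0L) next
    a <- spec$tab[[1L]]
    b <- spec$tab[[2L]]
    ignored <- ignored + length(setdiff(unique(c(a, b)), known_genes))
    flags <- add_flag(flags, ldgi_key %in% key(a, b), spec$flag)
  }

  tr <- read2(traits)
  if (!is.null(tr) && nrow(tr) > 0L) {
    trait_snps <- unique(tr[[1L]])
    supp_snps <- lapply(strsplit(ldgis$supporting_snp_pairs, ";", fixed = TRUE),
                        function(p) unique(unlist(strsplit(p, "|", fixed = TRUE))))
    flags <- add_flag(flags,
                      vapply(supp_snps,
                             function(s) any(s %in% trait_snps), logical(1L)),
                      "TRAIT_LINKED")
  }

  order_flags <- c("KNOWN_PPI", "KNOWN_COEXPRESSION", "TRAIT_LINKED")
  ldgis$known_evidence <- vapply(flags, function(f) {
    paste(order_flags[order_flags %in% f], collapse = ",")
  }, character(1L))
  attr(ldgis, "ignored_evidence_genes") <- ignored
  ldgis
}

parse_region <- function(region) {
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
  if (length(m) != 4L) {
    stop("malformed region string (expected chrom:start-end): ", region,
         call. = FALSE)
  }
  list(chrom = m[[2L]], start = as.integer(m[[3L]]), end = as.integer(m[[4L]]))
}

#' Filter long-range LD pairs
#'
#' Composable query with intersection semantics over the pair table.
#' Region strings use the half-open `chrom:start-end` convention and match
#' pairs with either SNP inside the region.
#'
#' @param pairs Pair tibble (plain or annotated).
#' @param snp_id,population Character vectors to match (either SNP for
#'   `snp_id`).
#' @param region Region string such as `"chr1:0-1000"` (0-based
#'   half-open).
#' @param r2_min Keep pairs at or above this r-squared tier (the 1.0 tier
#'   uses the complete-LD tolerance).
#' @return The filtered tibble.
#' @export
filter_pairs <- function(pairs, snp_id = NULL, region = NULL,
                         population = NULL, r2_min = NULL) {
  out <- pairs
  if (!is.null(snp_id)) {
    out <- out[out$snp1_id %in% snp_id | out$snp2_id %in% snp_id, ]
  }
  if (!is.null(region)) {
    rg <- parse_region(region)
    in_rg <- function(chrom, pos) {
      chrom == rg$chrom & pos >= rg$start & pos < rg$end
    }
    out <- out[in_rg(out$chrom1, out$pos1) | in_rg(out$chrom2, out$pos2), ]
  }
  if (!is.null(population)) out <- out[out$population %in% population, ]
  if (!is.null(r2_min)) {
    r2_min <- check_r2_min(r2_min)
    out <- out[vapply(out$r2, r2_passes, logical(1L), r2_min = r2_min), ]
  }
  out
}

#' Filter gene interactions
#'
#' @param ldgis Interaction tibble from [build_interactions()].
#' @param gene_id Keep interactions touching any of these genes.
#' @param category Keep these categories (subset of the six).
#' @param population Keep these populations.
#' @return The filtered tibble (intersection semantics).
#' @export
filter_interactions <- function(ldgis, gene_id = NULL, category = NULL,
                                population = NULL) {
  out <- ldgis
  if (!is.null(gene_id)) {
    out <- out[out$gene1 %in% gene_id | out$gene2 %in% gene_id, ]
  }
  if (!is.null(category)) {
    stopifnot(all(category %in% CATEGORIES))
    out <- out[out$category %in% category, ]
  }
  if (!is.null(population)) out <- out[out$population %in% population, ]
  out
}
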