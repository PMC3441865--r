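# End-to-end orchestration: load inputs, scan, annotate, build
# interactions, summarize. The run summary mirrors the per-population
# reporting layout of large haplotype-panel studies: individuals, LRLD
# pairs, SNPs involved, interactions, genes involved.

#' Load haplotype panels from VCF or haplotype tables
#'
#' @param vcf Optional phased VCF path (requires `popmap`).
#' @param haps Optional character vector of haplotype-table paths; names
#'   give the population labels (defaults to `haplotypes_<POP>` file-name
#'   convention, else the base file name).
#' @param popmap Population-map TSV path or data frame (for `vcf`).
#' @return Named list of [haplotype_panel] objects.
#' @export
load_panels <- function(vcf = NULL, haps = NULL, popmap = NULL) {
  if (is.null(vcf) && is.null(haps)) {
    stop("provide either a phased VCF or haplotype table(s)", call. = FALSE)
  }
  if (!is.null(vcf)) {
    if (is.null(popmap)) stop("a population map is required with a VCF",
                              call. = FALSE)
    return(read_phased_vcf(vcf, popmap))
  }
  labels <- names(haps)
  if (is.null(labels)) {
    base <- sub("\\.[^.]*$", "", basename(haps))
    labels <- sub("^haplotypes_", "", base)
  }
  panels <- lapply(seq_along(haps), function(i) {
    read_haplotype_table(haps[[i]], population_label = labels[[i]])
  })
  names(panels) <- labels
  panels
}

#' Run the full long-range LD pipeline
#'
#' Loads phased haplotypes, drops undersized populations, scans each
#' retained panel for long-range strong-LD SNP pairs, annotates the SNPs
#' involved against the gene models, builds the categorized gene
#' interactions, and (optionally) overlays external evidence. When
#' `out_dir` is given the pair table, annotated pair table, interaction
#' table and a JSON run summary are written there.
#'
#' @inheritParams load_panels
#' @param hotspots Hotspot BED3 path or a [hotspot_track].
#' @param gff3,fasta Gene-model GFF3 and genome FASTA paths (or a
#'   [gene_models] object via `gff3`, leaving `fasta` `NULL`).
#' @param r2_min Strong-LD threshold; one of 0.8, 0.9, 1.0.
#' @param min_individuals Population-size floor.
#' @param min_haplotypes Per-pair floor on jointly non-missing haplotypes.
#' @param ppi,coexp,traits Optional evidence inputs for
#'   [overlay_evidence()].
#' @param out_dir Optional output directory.
#' @return An object of class `ldgi_run`: list with `pairs`,
#'   `annotated_pairs`, `interactions`, `summary` (per-population counts),
#'   `params`, and `counters`.
#' @export
run_pipeline <- function(vcf = NULL, haps = NULL, popmap = NULL,
                         hotspots = NULL, gff3 = NULL, fasta = NULL,
                         r2_min = 0.8, min_individuals = 20L,
                         min_haplotypes = 40L,
                         ppi = NULL, coexp = NULL, traits = NULL,
                         out_dir = NULL) {
  r2_min <- check_r2_min(r2_min)
  panels <- load_panels(vcf = vcf, haps = haps, popmap = popmap)
  track <- if (inherits(hotspots, "hotspot_track")) hotspots
           else if (is.null(hotspots)) hotspot_track()
           else read_hotspots_bed(hotspots)
  models <- if (inherits(gff3, "gene_models")) gff3
            else if (is.null(gff3)) NULL
            else read_gene_models(gff3, fasta)

  kept <- filter_population_size(panels, min_individuals = min_individuals)
  pairs <- dplyr::bind_rows(lapply(kept, scan_population, track = track,
                                   r2_min = r2_min,
                                   min_haplotypes = min_haplotypes))

  snp_ids <- unique(c(pairs$snp1_id, pairs$snp2_id))
  annotations <- if (!is.null(models) && length(snp_ids) > 0L) {
    snps_all <- dplyr::distinct(
      dplyr::bind_rows(lapply(kept, function(p) p$snps)))
    annotate_snps(snps_all[snps_all$snp_id %in% snp_ids, ], models)
  } else {
    tibble(snp_id = character(), gene_id = character(),
           gene_name = character(), transcript_id = character(),
           feature = character(), utr_side = integer(),
           coding_effect = character())
  }
  annotated <- annotate_pairs(pairs, annotations)
  interactions <- build_interactions(annotated)
  interactions <- overlay_evidence(interactions, ppi = ppi, coexp = coexp,
                                   traits = traits)

  summary_tbl <- pipeline_summary(kept, pairs, interactions)
  params <- list(r2_min = r2_min, min_individuals = min_individuals,
                 min_haplotypes = min_haplotypes)
  counters <- list(
    dropped_populations = attr(kept, "dropped_populations"),
    self_pairs = attr(interactions, "self_pairs"),
    ignored_evidence_genes = attr(interactions, "ignored_evidence_genes")
  )
  result <- structure(
    list(pairs = pairs, annotated_pairs = annotated,
         interactions = interactions, summary = summary_tbl,
         params = params, counters = counters),
    class = "ldgi_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pairs_tsv(annotated, file.path(out_dir, "pairs_annotated.tsv"))
    write_pairs_tsv(pairs, file.path(out_dir, "pairs.tsv"))
    write_interactions_tsv(interactions,
                           file.path(out_dir, "interactions.tsv"))
    jsonlite::write_json(
      list(summary = summary_tbl, params = params, counters = counters),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

pipeline_summary <- function(panels, pairs, interactions) {
  dplyr::bind_rows(lapply(panels, function(p) {
    pop <- p$population_label
    pp <- pairs[pairs$population == pop, ]
    ii <- interactions[interactions$population == pop, ]
    tibble(
      population = pop,
      n_individuals = n_individuals(p),
      lrld_snp_pairs = nrow(pp),
      snps_in_pairs = length(unique(c(pp$snp1_id, pp$snp2_id))),
      ldgis = nrow(ii),
      genes_in_ldgis = length(unique(c(ii$gene1, ii$gene2)))
    )
  }))
}

#' @export
print.ldgi_run <- function(x, ...) {
  cat("<ldgi_run>\n")
  print(x$summary)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x An `ldgi_run` object.
#' @param ... Unused.
#' @return `tidy()` returns the interaction table; `glance()` the
#'   per-population summary counts with the thresholds used.
#' @method tidy ldgi_run
#' @export
tidy.ldgi_run <- function(x, ...) x$interactions

#' @rdname run_pipeline
#' @method glance ldgi_run
#' @export
glance.ldgi_run <- function(x, ...) {
  dplyr::mutate(x$summary,
                r2_min = x$params$r2_min,
                min_individuals = x$params$min_individuals,
                min_haplotypes = x$params$min_haplotypes)
}
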