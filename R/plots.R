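# ggplot2 views of the two result tables.

#' Plot the r-squared distribution of long-range LD pairs
#'
#' Histogram of pair r-squared values, faceted by population when several
#' are present, with the separation class (different chromosomes vs
#' hotspot-separated) mapped to fill.
#'
#' @param pairs Pair tibble from [scan_population()]/[scan_panels()].
#' @param binwidth Histogram bin width.
#' @return A ggplot object.
#' @export
plot_pair_r2 <- function(pairs, binwidth = 0.01) {
  sep_class <- ifelse(pairs$separation == "DIFF_CHROM",
                      "different chromosomes", "hotspot-separated")
  p <- ggplot2::ggplot(dplyr::mutate(pairs, sep_class = sep_class),
                       ggplot2::aes(x = .data$r2, fill = .data$sep_class)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 1,
                            position = "stack") +
    ggplot2::labs(x = expression(r^2), y = "SNP pairs",
                  fill = "separation") +
    ggplot2::theme_minimal()
  if (length(unique(pairs$population)) > 1L) {
    p <- p + ggplot2::facet_wrap(~population)
  }
  p
}

#' Plot gene-interaction counts by category
#'
#' Bar chart of interaction counts over the six feature categories,
#' split by coding subtype for CDS-involving categories.
#'
#' @param ldgis Interaction tibble from [build_interactions()].
#' @return A ggplot object.
#' @export
plot_interaction_categories <- function(ldgis) {
  d <- dplyr::mutate(ldgis,
                     category = factor(.data$category, levels = CATEGORIES),
                     subtype = ifelse(is.na(.data$coding_subtype), "none",
                                      .data$coding_subtype))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, fill = .data$subtype)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "gene interactions",
                  fill = "coding subtype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
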